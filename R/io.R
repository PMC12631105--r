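#' Read a CountMatrix from Matrix Market files with TSV sidecars
#'
#' Expects the 10x-style trio: a coordinate-format `.mtx` file (genes in rows,
#' cells in columns, 1-based indices), a genes TSV whose first column is the
#' gene id, and a cells TSV with at least a `cell_id` column (additional
#' metadata columns `sample`, `group`, `tissue`, `celltype` are carried
#' along). Sidecar ordering is authoritative for the gene/cell axes.
#'
#' @param counts_path path to the `.mtx` file.
#' @param genes_path path to the gene sidecar TSV.
#' @param cells_path path to the cell sidecar TSV (with header).
#' @return a [CountMatrix].
#' @export
read_mtx <- function(counts_path, genes_path, cells_path) {
  for (p in c(counts_path, genes_path, cells_path))
    if (!file.exists(p)) stop("file not found: ", p)
  counts <- Matrix::readMM(counts_path)
  genes <- utils::read.delim(genes_path, header = FALSE, stringsAsFactors = FALSE)
  cells <- utils::read.delim(cells_path, header = TRUE, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cells))
    stop("cells sidecar must have a cell_id column")
  if (nrow(genes) != nrow(counts))
    stop("format error: MTX declares ", nrow(counts), " genes but genes sidecar has ",
         nrow(genes), " rows")
  if (nrow(cells) != ncol(counts))
    stop("format error: MTX declares ", ncol(counts), " cells but cells sidecar has ",
         nrow(cells), " rows")
  gid <- as.character(genes[[1]])
  if (anyDuplicated(gid)) stop("format error: duplicate gene ids in sidecar")
  if (anyDuplicated(cells$cell_id)) stop("format error: duplicate cell ids in sidecar")
  CountMatrix(counts, gene_ids = gid, cell_ids = cells$cell_id, cell_meta = cells)
}

#' Write a CountMatrix as Matrix Market + TSV sidecars
#'
#' @param m a [CountMatrix].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written (`matrix.mtx`, `genes.tsv`, `cells.tsv`).
#' @export
write_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  Matrix::writeMM(Matrix::drop0(m$counts), paths[1])
  utils::write.table(data.frame(gene_id = gene_ids(m)), paths[2],
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(m$cell_meta, paths[3],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Quality-control filter on cells
#'
#' Retains cells with a detected-gene count (genes with count > 0) between
#' `min_genes` and `max_genes` inclusive and a mitochondrial fraction (counts
#' on "MT-"-prefixed genes over total counts, computed on raw counts) at or
#' below `max_mito`. Defaults follow the standard single-cell thresholds of
#' 200/8000 detected genes and 10% mitochondrial content. The gene axis is
#' never touched.
#'
#' @param m a [CountMatrix].
#' @param min_genes minimum detected genes, inclusive.
#' @param max_genes maximum detected genes, inclusive.
#' @param max_mito maximum mitochondrial fraction, inclusive.
#' @return list with `matrix` (the filtered CountMatrix) and `report`, a
#'   data.frame with per-cell `detected_genes`, `mito_fraction`, `pass` plus
#'   the thresholds in its attributes.
#' @export
qc_filter <- function(m, min_genes = 200, max_genes = 8000, max_mito = 0.10) {
  detected <- Matrix::colSums(m$counts > 0)
  tot <- Matrix::colSums(m$counts)
  mito_idx <- startsWith(gene_ids(m), "MT-")
  mito <- if (any(mito_idx)) Matrix::colSums(m$counts[mito_idx, , drop = FALSE]) else
    numeric(ncol(m$counts))
  mito_frac <- ifelse(tot > 0, mito / tot, 0)
  pass <- detected >= min_genes & detected <= max_genes & mito_frac <= max_mito
  report <- data.frame(cell_id = cell_ids(m),
                       detected_genes = as.integer(detected),
                       mito_fraction = mito_frac,
                       pass = pass, stringsAsFactors = FALSE)
  attr(report, "thresholds") <- list(min_genes = min_genes, max_genes = max_genes,
                                     max_mito = max_mito)
  if (!any(pass)) warning("qc_filter removed all cells")
  list(matrix = subset_cm(m, cells = which(pass)), report = report)
}

#' Remove mitochondrial and ribosomal genes
#'
#' Drops genes whose ids start with "MT-", "RPL" or "RPS"; idempotent and a
#' no-op when no such genes are present. Cells are untouched.
#'
#' @param m a [CountMatrix].
#' @return the CountMatrix without mito/ribo genes.
#' @export
strip_mito_ribo <- function(m) {
  g <- gene_ids(m)
  keep <- !(startsWith(g, "MT-") | startsWith(g, "RPL") | startsWith(g, "RPS"))
  if (all(keep)) return(m)
  subset_cm(m, genes = which(keep))
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: name, description, then members. Duplicate
#' members within a line are dropped (sets are sets); line order is preserved.
#'
#' @param path path to a `.gmt` file.
#' @return a named list of character vectors of gene ids, with each set's
#'   description in a "description" attribute vector on the list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("format error: GMT line ", i, " has fewer than 3 fields")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    sets[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
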