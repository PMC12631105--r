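#' Construct a CountMatrix
#'
#' The central container of the package: a sparse genes x cells matrix of
#' non-negative integer counts together with per-cell metadata. Gene and cell
#' identifiers live in the dimnames of the sparse matrix; `cell_meta` is a
#' data.frame keyed by `cell_id` carrying at least the columns `sample`,
#' `group`, `tissue` and `celltype` (missing columns are filled with NA).
#'
#' @param counts matrix or sparse Matrix, genes in rows, cells in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(counts)`).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `colnames(counts)`).
#' @param cell_meta data.frame of per-cell metadata with a `cell_id` column,
#'   or NULL for empty metadata.
#' @return An object of class `CountMatrix`.
#' @export
CountMatrix <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts), cell_meta = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length (", length(gene_ids), ") != nrow(counts) (", nrow(counts), ")")
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length (", length(cell_ids), ") != ncol(counts) (", ncol(counts), ")")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(gene_ids, cell_ids)

  meta_cols <- c("sample", "group", "tissue", "celltype")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  } else {
    cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(cell_meta)) stop("cell_meta needs a cell_id column")
    if (!setequal(cell_meta$cell_id, cell_ids))
      stop("cell_meta cell_ids do not match matrix cell_ids")
    cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  }
  for (cc in meta_cols) if (!cc %in% names(cell_meta)) cell_meta[[cc]] <- NA_character_
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  ns <- length(unique(stats::na.omit(x$cell_meta$sample)))
  if (ns > 0) cat("  samples:", ns, "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Gene identifiers of a CountMatrix
#' @param m a CountMatrix.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(m) rownames(m$counts)

#' Cell identifiers of a CountMatrix
#' @param m a CountMatrix.
#' @return character vector of cell ids.
#' @export
cell_ids <- function(m) colnames(m$counts)

#' Subset a CountMatrix by genes and/or cells
#'
#' @param m a CountMatrix.
#' @param genes gene index/logical/character vector, or NULL for all.
#' @param cells cell index/logical/character vector, or NULL for all.
#' @return the subsetted CountMatrix; metadata rows follow the cells.
#' @export
subset_cm <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- seq_len(nrow(m$counts))
  if (is.null(cells)) cells <- seq_len(ncol(m$counts))
  counts <- m$counts[genes, cells, drop = FALSE]
  meta <- m$cell_meta[match(colnames(counts), m$cell_meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, cell_meta = meta), class = "CountMatrix")
}

#' Counts-per-10k log-normalization
#'
#' Scales each cell to 10,000 total counts and applies log1p — the
#' conventional normalization expected by the scoring functions.
#'
#' @param m a CountMatrix.
#' @param scale_factor library-size target (default 1e4).
#' @return a dgCMatrix of log-normalized expression, genes x cells.
#' @export
lognorm <- function(m, scale_factor = 1e4) {
  tot <- Matrix::colSums(m$counts)
  tot[tot == 0] <- 1
  x <- m$counts %*% Matrix::Diagonal(x = scale_factor / tot)
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(m$counts)
  methods::as(x, "CsparseMatrix")
}
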