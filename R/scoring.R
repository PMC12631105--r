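#' Control-gene module score
#'
#' The classic bin-matched signature score: genes are placed into `n_bins`
#' equal-frequency bins by mean log-normalized expression (ties to the lower
#' bin); for each signature gene, `n_ctrl` control genes are drawn from its
#' bin (without replacement when the bin is large enough, otherwise with
#' replacement); the per-cell score is the mean expression of the signature
#' genes minus the mean expression of the drawn control multiset.
#'
#' @param m a [CountMatrix]; expression is log-normalized internally
#'   (counts-per-10k, log1p).
#' @param signature character vector of gene ids; absent genes are dropped
#'   with a warning.
#' @param n_bins number of expression bins (default 24, capped at the gene
#'   count).
#' @param n_ctrl control genes per signature gene (default 100).
#' @param seed integer seed fixing the control draw.
#' @return named numeric vector, one score per cell.
#' @export
module_score <- function(m, signature, n_bins = 24, n_ctrl = 100, seed = 1L) {
  expr <- lognorm(m)
  present <- intersect(signature, rownames(expr))
  if (length(present) < length(signature))
    warning(length(signature) - length(present), " signature gene(s) absent, dropped")
  if (length(present) == 0) stop("empty signature after filtering")
  G <- nrow(expr)
  n_bins <- min(n_bins, G)
  means <- Matrix::rowMeans(expr)
  rk <- rank(means, ties.method = "min")
  bin <- floor((rk - 1) * n_bins / G) + 1
  names(bin) <- rownames(expr)

  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
    else sample(pool, n_ctrl, replace = TRUE)
  }))
  sig_mean <- Matrix::colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(as.matrix(expr[ctrl, , drop = FALSE]))
  stats::setNames(as.numeric(sig_mean - ctrl_mean), colnames(expr))
}

#' Rank-AUC gene-set score
#'
#' Per cell, genes are ranked by expression (descending; ties broken by gene
#' order after one seeded shuffle of the gene axis, fixed for the whole run)
#' and the score is the area under the gene set's recovery curve within the
#' top `ceiling(top_fraction * G)` ranks, normalized to `[0, 1]` by the
#' maximal achievable area. Invariant under monotone transforms of
#' expression, so it is computed on raw counts.
#'
#' @param m a [CountMatrix].
#' @param gene_set character vector of gene ids; must intersect the matrix
#'   genes.
#' @param top_fraction fraction of the ranking considered (default 0.05).
#' @param seed seed for the tie-breaking shuffle.
#' @return named numeric vector in `[0, 1]`, one AUC per cell.
#' @export
rank_auc <- function(m, gene_set, top_fraction = 0.05, seed = 1L) {
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0, 1]")
  genes <- gene_ids(m)
  present <- intersect(gene_set, genes)
  if (length(present) == 0) stop("gene_set disjoint from matrix genes")
  G <- length(genes)
  thresh <- ceiling(top_fraction * G)
  set.seed(seed)
  perm <- sample.int(G)
  x <- as.matrix(m$counts)[perm, , drop = FALSE]
  set_idx <- which(rownames(x) %in% present)
  s <- min(length(set_idx), thresh)
  max_area <- s * (s + 1) / 2 + s * (thresh - s)
  auc <- apply(x, 2, function(col) {
    rk <- rank(-col, ties.method = "first")
    pos <- sort(rk[set_idx])
    pos <- pos[pos <= thresh]
    if (length(pos) == 0) return(0)
    # area under the step recovery curve evaluated at ranks 1..thresh
    sum(thresh - pos + 1) / max_area
  })
  stats::setNames(auc, cell_ids(m))
}

#' Pseudobulk aggregation
#'
#' Gene-wise count sums per group of cells.
#'
#' @param m a [CountMatrix].
#' @param by metadata column to group cells by (default "sample").
#' @return dense numeric matrix genes x groups.
#' @export
pseudobulk <- function(m, by = "sample") {
  if (!by %in% names(m$cell_meta)) stop("unknown grouping column: ", by)
  g <- factor(m$cell_meta[[by]])
  design <- Matrix::sparseMatrix(i = seq_along(g), j = as.integer(g), x = 1,
                                 dims = c(length(g), nlevels(g)))
  out <- as.matrix(m$counts %*% design)
  dimnames(out) <- list(gene_ids(m), levels(g))
  out
}

#' Luminal/basal call from per-sample signature scores
#'
#' Compares per-sample mean rank-AUC scores of the basal and luminal gene
#' sets; a sample is called basal when its basal score exceeds its luminal
#' score, luminal when lower, and indeterminate on an exact tie. This is a
#' score-comparison approximation to nearest-centroid molecular subtyping.
#'
#' @param scores_basal,scores_luminal named numeric vectors over the same
#'   samples.
#' @return data.frame with sample, basal_score, luminal_score, margin
#'   (basal - luminal), label.
#' @export
call_luminal_basal <- function(scores_basal, scores_luminal) {
  if (!setequal(names(scores_basal), names(scores_luminal)))
    stop("score vectors must cover the same samples")
  samples <- names(scores_basal)
  lum <- scores_luminal[samples]
  margin <- scores_basal - lum
  label <- ifelse(margin > 0, "basal", ifelse(margin < 0, "luminal", "indeterminate"))
  data.frame(sample = samples, basal_score = as.numeric(scores_basal),
             luminal_score = as.numeric(lum), margin = as.numeric(margin),
             label = as.character(label), stringsAsFactors = FALSE, row.names = NULL)
}

#' Four-gene MHC-II positivity gate
#'
#' A cell is MHC-II positive iff it has detectable expression (count > 0) of
#' all four gate genes, by default HLA-DRA, HLA-DRB1, HLA-DPA1 and HLA-DPB1.
#' Evaluated on raw counts; any zero-preserving normalization gives the same
#' call.
#'
#' @param m a [CountMatrix].
#' @param genes exactly four gate gene ids, all present in the matrix.
#' @return list with `positive` (named logical per cell), `genes`, and
#'   `fraction_by_sample` (data.frame: sample, n_cells, n_positive,
#'   fraction).
#' @export
mhc2_gate <- function(m, genes = c("HLA-DRA", "HLA-DRB1", "HLA-DPA1", "HLA-DPB1")) {
  if (length(genes) != 4) stop("the gate takes exactly four genes")
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing) > 0)
    stop("gate gene(s) missing from matrix: ", paste(missing, collapse = ", "))
  sub <- m$counts[genes, , drop = FALSE]
  positive <- Matrix::colSums(sub > 0) == 4
  names(positive) <- cell_ids(m)
  samp <- m$cell_meta$sample
  tab <- do.call(rbind, lapply(split(seq_along(positive), samp), function(idx)
    data.frame(n_cells = length(idx), n_positive = sum(positive[idx]))))
  frac <- data.frame(sample = rownames(tab), tab,
                     fraction = tab$n_positive / tab$n_cells,
                     stringsAsFactors = FALSE, row.names = NULL)
  list(positive = positive, genes = genes, fraction_by_sample = frac)
}
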