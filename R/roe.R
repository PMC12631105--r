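#' Observed/expected (Ro/e) cell-type enrichment
#'
#' For a clusters x groups contingency table of cell counts, the expected
#' count under the chi-square independence model is
#' `rowsum * colsum / total`, and Ro/e is the elementwise ratio of observed
#' to expected. A ratio above 1 flags enrichment of the cluster in that
#' group, below 1 depletion; exactly 1 is labeled neutral. Columns with zero
#' total have undefined ratios and are reported as NA.
#'
#' @param counts nonnegative integer matrix or table, clusters in rows,
#'   phenotype groups in columns.
#' @return an object of class `roe_table`: list with `observed`, `expected`,
#'   `ratio` and `label` matrices ("enriched"/"depleted"/"neutral"/NA).
#' @export
roe <- function(counts) {
  obs <- as.matrix(counts)
  if (any(obs < 0)) stop("counts must be nonnegative")
  total <- sum(obs)
  if (total <= 0) stop("total count must be > 0")
  rs <- rowSums(obs); cs <- colSums(obs)
  expected <- outer(rs, cs) / total
  ratio <- obs / expected
  ratio[, cs == 0] <- NA_real_
  label <- matrix(NA_character_, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  label[!is.na(ratio) & ratio > 1] <- "enriched"
  label[!is.na(ratio) & ratio < 1] <- "depleted"
  label[!is.na(ratio) & ratio == 1] <- "neutral"
  structure(list(observed = obs, expected = expected, ratio = ratio,
                 label = label), class = "roe_table")
}

#' @export
print.roe_table <- function(x, digits = 3, ...) {
  cat("Ro/e table (", nrow(x$observed), " clusters x ", ncol(x$observed),
      " groups)\n", sep = "")
  print(round(x$ratio, digits))
  invisible(x)
}

#' Ro/e from per-cell metadata
#'
#' Convenience wrapper tabulating two metadata columns of a [CountMatrix]
#' into the contingency table consumed by [roe].
#'
#' @param m a [CountMatrix].
#' @param cluster_col,group_col metadata column names (default celltype by
#'   group).
#' @return a `roe_table`.
#' @export
roe_from_meta <- function(m, cluster_col = "celltype", group_col = "group") {
  for (cc in c(cluster_col, group_col))
    if (!cc %in% names(m$cell_meta)) stop("unknown metadata column: ", cc)
  roe(table(m$cell_meta[[cluster_col]], m$cell_meta[[group_col]]))
}
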