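#' Normalize a cell type's spot abundances to a distribution
#'
#' @param a a SpotAbundance data.frame (columns spot_id, row, col, one column
#'   per cell type) or a numeric abundance vector.
#' @param celltype column name when `a` is a data.frame.
#' @param pseudocount nonnegative value added to every spot before
#'   normalization; with a positive pseudocount the result is strictly
#'   positive, making KL divergences finite.
#' @return probability vector over spots (sums to 1).
#' @export
to_distribution <- function(a, celltype = NULL, pseudocount = 0) {
  v <- if (is.data.frame(a)) {
    if (is.null(celltype) || !celltype %in% names(a))
      stop("celltype column not found: ", celltype)
    a[[celltype]]
  } else as.numeric(a)
  if (length(v) < 1) stop("need at least one spot")
  if (any(v < 0)) stop("abundances must be nonnegative")
  v <- v + pseudocount
  s <- sum(v)
  if (s <= 0) stop("all-zero abundance with zero pseudocount")
  v / s
}

abundance_columns <- function(a) setdiff(names(a), c("spot_id", "row", "col", "sample"))

default_pseudocount <- function(a) {
  cols <- abundance_columns(a)
  1e-9 * mean(as.matrix(a[, cols, drop = FALSE]))
}

#' Symmetric Kullback-Leibler divergence
#'
#' `0.5 * (KL(p||q) + KL(q||p))` in natural-log units (nats). Zero iff the
#' distributions are equal; requires strictly positive inputs on a shared
#' support.
#'
#' @param p,q probability vectors of equal length.
#' @return nonnegative scalar (nats).
#' @export
symmetric_kl <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must share the same support length")
  if (any(p <= 0) || any(q <= 0))
    stop("p and q must be strictly positive (use a pseudocount)")
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}

#' Spatial colocalization test by subsampled symmetric KL
#'
#' The observed statistic is the symmetric KL divergence between the two
#' cell types' spot distributions over all spots. The null is built by
#' repeatedly drawing an independent uniform subsample of
#' `ceiling(frac * n_spots)` spots (without replacement) for each cell type,
#' restricting both to the intersection of the two subsampled spot sets,
#' renormalizing, and recomputing the symmetric KL; the empirical p-value is
#' the fraction of null values strictly exceeding the observed one. Low
#' observed KL indicates colocalization.
#'
#' @param a SpotAbundance data.frame.
#' @param type1,type2 cell-type column names.
#' @param n_perm number of subsampling permutations (default 1000).
#' @param frac subsample fraction in (0, 1] (default 0.8).
#' @param pseudocount added before normalization; default
#'   `1e-9 * mean(abundance)`.
#' @param seed integer seed; the full null is reproducible.
#' @param add_one if TRUE use the (b + 1) / (n + 1) estimator instead of the
#'   plain fraction (which can return an exact 0).
#' @return object of class `coloc_result`: observed sKL, null values,
#'   empirical p, and the parameters used.
#' @export
coloc_permutation <- function(a, type1, type2, n_perm = 1000, frac = 0.8,
                              pseudocount = NULL, seed = 1L, add_one = FALSE) {
  cols <- abundance_columns(a)
  for (tt in c(type1, type2))
    if (!tt %in% cols) stop("cell type column not found: ", tt)
  n_spots <- nrow(a)
  if (n_spots < 5) stop("need at least 5 spots")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (is.null(pseudocount)) pseudocount <- default_pseudocount(a)

  v1 <- a[[type1]]; v2 <- a[[type2]]
  observed <- symmetric_kl(to_distribution(v1, pseudocount = pseudocount),
                           to_distribution(v2, pseudocount = pseudocount))
  m_sub <- ceiling(frac * n_spots)
  set.seed(seed)
  null_vals <- numeric(n_perm)
  redraws <- 0L
  i <- 1L
  while (i <= n_perm) {
    s1 <- sample.int(n_spots, m_sub)
    s2 <- sample.int(n_spots, m_sub)
    common <- intersect(s1, s2)
    if (length(common) == 0) {
      redraws <- redraws + 1L
      if (redraws > n_perm)
        stop("subsample redraw budget exceeded (empty intersections)")
      message("empty subsample intersection; permutation redrawn")
      next
    }
    null_vals[i] <- symmetric_kl(
      to_distribution(v1[common], pseudocount = pseudocount),
      to_distribution(v2[common], pseudocount = pseudocount))
    i <- i + 1L
  }
  p <- if (add_one) (sum(null_vals > observed) + 1) / (n_perm + 1)
       else sum(null_vals > observed) / n_perm
  structure(list(type1 = type1, type2 = type2, observed = observed,
                 null = null_vals, p_value = p, n_perm = n_perm, frac = frac,
                 pseudocount = pseudocount, seed = seed, redraws = redraws),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization ", x$type1, " vs ", x$type2, ": sKL = ",
      signif(x$observed, 4), " nats, empirical p = ", signif(x$p_value, 4),
      " (", x$n_perm, " permutations, frac = ", x$frac, ")\n", sep = "")
  invisible(x)
}

#' Pairwise colocalization over all cell types
#'
#' @param a SpotAbundance data.frame.
#' @param n_perm,frac,pseudocount,seed as in [coloc_permutation].
#' @return list with symmetric matrices `skl` and `p` over cell types.
#' @export
coloc_all_pairs <- function(a, n_perm = 1000, frac = 0.8, pseudocount = NULL,
                            seed = 1L) {
  cols <- abundance_columns(a)
  k <- length(cols)
  skl <- matrix(0, k, k, dimnames = list(cols, cols))
  p <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  pair_seed <- seed
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    pair_seed <- pair_seed + 1L
    r <- coloc_permutation(a, cols[i], cols[j], n_perm = n_perm, frac = frac,
                           pseudocount = pseudocount, seed = pair_seed)
    skl[i, j] <- skl[j, i] <- r$observed
    p[i, j] <- p[j, i] <- r$p_value
  }
  list(skl = skl, p = p)
}

#' NMF compartments of spot x cell-type abundances
#'
#' Factorizes the spots x cell-type abundance matrix into `n_factors`
#' nonnegative co-occurrence compartments; each factor's cell-type weights
#' are also returned normalized to a maximum of 1 for display.
#'
#' @param a SpotAbundance data.frame (possibly concatenated across slides).
#' @param n_factors number of compartments; must be < number of cell types.
#' @param seed integer seed.
#' @param max_iter,tol NMF controls.
#' @return list with `spot_loadings` (spots x factors), `type_weights`
#'   (cell types x factors), `type_weights_scaled` (max 1 per factor), and
#'   `error`.
#' @export
compartment_nmf <- function(a, n_factors, seed = 1L, max_iter = 2000, tol = 1e-6) {
  cols <- abundance_columns(a)
  if (n_factors >= length(cols))
    stop("n_factors must be < number of cell types (", length(cols), ")")
  X <- t(as.matrix(a[, cols, drop = FALSE]))   # types x spots
  set.seed(seed)
  best <- NULL
  for (r in 1:5) {   # few restarts; keep the best fit
    fit <- run_nmf_once(X, n_factors, max_iter, tol)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  tw <- best$W                                  # types x factors
  dimnames(tw) <- list(cols, paste0("factor", seq_len(n_factors)))
  sl <- t(best$H)                               # spots x factors
  dimnames(sl) <- list(a$spot_id, colnames(tw))
  scl <- apply(tw, 2, function(w) if (max(w) > 0) w / max(w) else w)
  list(spot_loadings = sl, type_weights = tw, type_weights_scaled = scl,
       error = best$error)
}

#' Read / write spot-abundance TSV
#'
#' @param path TSV with columns spot_id, row, col and one column per cell
#'   type.
#' @return data.frame SpotAbundance.
#' @export
read_spot_abundance <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("spot_id", "row", "col")
  if (!all(need %in% names(a)))
    stop("spot abundance TSV needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(a$spot_id)) stop("duplicate spot ids")
  cols <- abundance_columns(a)
  if (any(as.matrix(a[, cols, drop = FALSE]) < 0)) stop("abundances must be nonnegative")
  a
}

#' @rdname read_spot_abundance
#' @param a SpotAbundance data.frame to write.
#' @export
write_spot_abundance <- function(a, path) {
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
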