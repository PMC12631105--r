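#' Preprocess a CountMatrix for NMF
#'
#' Applies the standard chain expected by consensus NMF: mito/ribo genes
#' removed, counts-per-10k per cell, highly-variable-gene selection (top
#' `n_hvg` by variance), and per-gene scaling to unit variance. Scaling is
#' multiplicative (no centering) so the result stays nonnegative.
#'
#' @param m a [CountMatrix].
#' @param n_hvg number of highly variable genes to keep (default 2000; all
#'   genes kept if fewer are available).
#' @return dense numeric matrix, genes x cells, with dimnames.
#' @export
nmf_preprocess <- function(m, n_hvg = 2000) {
  m <- strip_mito_ribo(m)
  tot <- Matrix::colSums(m$counts)
  tot[tot == 0] <- 1
  x <- as.matrix(m$counts %*% Matrix::Diagonal(x = 1e4 / tot))
  rownames(x) <- gene_ids(m)
  colnames(x) <- cell_ids(m)
  v <- apply(x, 1, stats::var)
  if (nrow(x) > n_hvg) {
    keep <- order(v, decreasing = TRUE)[seq_len(n_hvg)]
    keep <- sort(keep)
    x <- x[keep, , drop = FALSE]
    v <- v[keep]
  }
  sd_g <- sqrt(v)
  sd_g[sd_g == 0] <- 1
  x / sd_g
}

run_nmf_once <- function(X, k, max_iter = 500, tol = 1e-4) {
  G <- nrow(X); N <- ncol(X)
  scale0 <- sqrt(mean(X) / k)
  W0 <- matrix(stats::runif(G * k, 0, 2 * scale0) + 1e-6, G, k)
  H0 <- matrix(stats::runif(k * N, 0, 2 * scale0) + 1e-6, k, N)
  nmf_mu(X, W0, H0, as.integer(max_iter), tol, 10L)
}

#' Consensus non-negative matrix factorization at a fixed rank
#'
#' Runs `n_replicates` multiplicative-update NMF fits from distinct random
#' initializations, pools the replicate gene spectra (L2-normalized),
#' removes outlier spectra by a local-density rule (mean distance to the
#' `density_knn` nearest neighbour spectra above the `density_quantile`
#' percentile), partitions the survivors into `k` clusters by k-means, takes
#' the per-cluster elementwise median as the consensus spectrum, and re-fits
#' the usage matrix by nonnegative least squares against the consensus
#' spectra. Fully deterministic given `seed`.
#'
#' @param x a [CountMatrix] (preprocessed internally via [nmf_preprocess])
#'   or an already-preprocessed nonnegative numeric matrix, genes x cells.
#' @param k factorization rank (number of programs); must satisfy
#'   `k < min(G, N)`.
#' @param n_replicates number of random restarts pooled into the consensus.
#' @param seed integer seed.
#' @param top_genes length of each program's ranked top-gene list.
#' @param max_iter,tol NMF iteration budget and relative-error tolerance.
#' @param density_knn,density_quantile outlier-filter parameters.
#' @param sample_id provenance label attached to the programs.
#' @return list with `programs` (length-k list of `GeneProgram` lists:
#'   `sample_id`, `k`, `program_index`, `spectrum`, `top_genes`), `usage`
#'   (cells x k nonnegative matrix), and `error` (Frobenius reconstruction
#'   error of the consensus solution).
#' @export
consensus_nmf <- function(x, k, n_replicates = 10, seed = 1L,
                          top_genes = 50, max_iter = 500, tol = 1e-4,
                          density_knn = 15, density_quantile = 0.9,
                          sample_id = "sample") {
  X <- if (inherits(x, "CountMatrix")) nmf_preprocess(x) else as.matrix(x)
  if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
  if (any(X < 0)) stop("NMF input must be nonnegative")
  G <- nrow(X); N <- ncol(X)
  if (k >= min(G, N)) stop("k must be < min(genes, cells) = ", min(G, N))
  if (n_replicates < 1) stop("n_replicates must be >= 1")

  set.seed(seed)
  spectra <- vector("list", n_replicates)
  worst_err <- -Inf
  for (r in seq_len(n_replicates)) {
    fit <- run_nmf_once(X, k, max_iter, tol)
    if (!all(is.finite(fit$W))) { warning("non-convergent replicate dropped"); next }
    worst_err <- max(worst_err, fit$error)
    Wn <- fit$W
    nrm <- sqrt(colSums(Wn^2)); nrm[nrm == 0] <- 1
    spectra[[r]] <- t(Wn) / nrm   # rows = unit-norm spectra
  }
  S <- do.call(rbind, spectra)
  if (is.null(S) || nrow(S) < k) stop("too few convergent replicates for k = ", k)

  # local-density outlier filter on pooled spectra
  if (nrow(S) > k + 2) {
    d <- as.matrix(stats::dist(S))
    knn <- min(density_knn, nrow(S) - 1)
    mean_knn <- apply(d, 1, function(r) mean(sort(r)[2:(knn + 1)]))
    keep <- mean_knn <= stats::quantile(mean_knn, density_quantile)
    if (sum(keep) >= k) S <- S[keep, , drop = FALSE]
  }

  cl <- stats::kmeans(S, centers = k, nstart = 10, iter.max = 100)$cluster
  Wc <- sapply(seq_len(k), function(j) {
    apply(S[cl == j, , drop = FALSE], 2, stats::median)
  })  # G x k consensus spectra
  Wc <- pmax(Wc, 0)

  H0 <- matrix(mean(X) / max(mean(Wc), 1e-12) / k, k, N)
  ref <- nmf_fit_usage(X, Wc, H0, as.integer(max_iter), tol, 10L)
  H <- ref$H

  ord <- order(rowSums(H), decreasing = TRUE)   # programs by total usage
  Wc <- Wc[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  programs <- lapply(seq_len(k), function(j) {
    sp <- stats::setNames(Wc[, j], rownames(X))
    tg <- names(sp)[order(-sp, names(sp))][seq_len(min(top_genes, G))]
    list(sample_id = sample_id, k = k, program_index = j,
         spectrum = sp, top_genes = tg)
  })
  usage <- t(H)
  dimnames(usage) <- list(colnames(X), paste0("k", k, "_p", seq_len(k)))
  list(programs = programs, usage = usage, error = ref$error,
       worst_replicate_error = worst_err)
}

#' Configuration for the per-sample program stage
#'
#' @param k_min,k_max inclusive range of factorization ranks (default 4..12,
#'   which yields `sum(4:12) = 72` programs per sample).
#' @param n_replicates random restarts per rank (default 200).
#' @param top_genes_per_program ranked top-gene list length (default 50).
#' @param n_hvg highly-variable genes kept before NMF.
#' @param max_iter,tol NMF iteration controls.
#' @param seed integer seed.
#' @return a `program_set_config` list.
#' @export
program_set_config <- function(k_min = 4, k_max = 12, n_replicates = 200,
                               top_genes_per_program = 50, n_hvg = 2000,
                               max_iter = 500, tol = 1e-4, seed = 1L) {
  if (k_min < 2) stop("k_min must be >= 2")
  if (k_max < k_min) stop("k_max must be >= k_min")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_replicates = as.integer(n_replicates),
                 top_genes_per_program = as.integer(top_genes_per_program),
                 n_hvg = as.integer(n_hvg), max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "program_set_config")
}

#' Run consensus NMF across the full rank range for one sample
#'
#' Preprocesses once, then concatenates [consensus_nmf] programs for every
#' rank in `[k_min, k_max]`; with the default range 4..12 this yields 72
#' programs for the sample.
#'
#' @param m a [CountMatrix] holding one sample's cells.
#' @param cfg a [program_set_config].
#' @param sample_id provenance label (defaults to the metadata sample if
#'   unique).
#' @return flat list of `GeneProgram` lists with (sample_id, k, index)
#'   provenance.
#' @export
programs_for_sample <- function(m, cfg = program_set_config(), sample_id = NULL) {
  if (is.null(sample_id)) {
    ss <- unique(stats::na.omit(m$cell_meta$sample))
    sample_id <- if (length(ss) == 1) ss else "sample"
  }
  X <- nmf_preprocess(m, n_hvg = cfg$n_hvg)
  out <- list()
  for (k in seq(cfg$k_min, cfg$k_max)) {
    res <- consensus_nmf(X, k, n_replicates = cfg$n_replicates,
                         seed = cfg$seed + k, top_genes = cfg$top_genes_per_program,
                         max_iter = cfg$max_iter, tol = cfg$tol,
                         sample_id = sample_id)
    out <- c(out, res$programs)
  }
  out
}

top_gene_sets <- function(programs) lapply(programs, `[[`, "top_genes")

#' Select robust programs across ranks and samples
#'
#' A program is robust iff (a) its top-gene list shares at least
#' `intra_overlap_min` genes with some program of the same sample at a
#' different rank, and (b) shares at least `inter_overlap_min` genes with
#' some program of a different sample.
#'
#' @param programs flat list of `GeneProgram`s pooled over all samples.
#' @param intra_overlap_min within-sample cross-rank overlap threshold
#'   (default 35 of the top 50).
#' @param inter_overlap_min cross-sample overlap threshold (default 10).
#' @return the retained sublist, provenance intact; empty (with a warning)
#'   when only one sample is represented.
#' @export
select_robust <- function(programs, intra_overlap_min = 35, inter_overlap_min = 10) {
  if (length(programs) == 0) return(list())
  samples <- vapply(programs, `[[`, character(1), "sample_id")
  ks <- vapply(programs, `[[`, numeric(1), "k")
  if (length(unique(samples)) < 2) {
    warning("only one sample represented; cross-sample robustness unsatisfiable")
    return(list())
  }
  sets <- top_gene_sets(programs)
  n <- length(programs)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ov <- vapply(seq_len(n), function(j)
      if (j == i) 0L else length(intersect(sets[[i]], sets[[j]])), integer(1))
    intra_ok <- any(ov >= intra_overlap_min & samples == samples[i] & ks != ks[i])
    inter_ok <- any(ov >= inter_overlap_min & samples != samples[i])
    keep[i] <- intra_ok && inter_ok
  }
  programs[keep]
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors treated as sets.
#' @return `|a n b| / |a u b|`; 0 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

mp_signature <- function(members, signature_size) {
  # genes ranked by how many member top-gene lists contain them,
  # ties by summed spectrum weight, then lexicographic gene id
  genes <- unlist(lapply(members, `[[`, "top_genes"))
  counts <- table(genes)
  gname <- names(counts)
  wsum <- vapply(gname, function(g)
    sum(vapply(members, function(p) {
      w <- p$spectrum[g]
      if (is.na(w)) 0 else unname(w)
    }, numeric(1))), numeric(1))
  ord <- order(-as.integer(counts), -wsum, gname)
  gname[ord][seq_len(min(signature_size, length(gname)))]
}

#' Cluster robust programs into meta-programs
#'
#' Greedy founder clustering on top-gene overlap: seed with the program of
#' largest summed Jaccard similarity to all others, grow by repeatedly adding
#' the unassigned program with the largest gene overlap to the current
#' signature while the overlap is at least `min_join_overlap`, recomputing
#' the signature (the `signature_size` genes occurring in the most member
#' top-gene lists; ties by summed spectrum weight then gene id) after each
#' addition. Clusters whose members all come from one sample are discarded.
#'
#' @param robust list of robust `GeneProgram`s.
#' @param min_join_overlap minimum gene overlap with the running signature
#'   for a program to join (default 10).
#' @param signature_size meta-program signature length (default 30).
#' @return list of `MetaProgram`s: `mp_id`, `members`, `signature`,
#'   `member_samples`.
#' @export
cluster_metaprograms <- function(robust, min_join_overlap = 10, signature_size = 30) {
  if (length(robust) == 0) return(list())
  all_genes <- unique(unlist(lapply(robust, `[[`, "top_genes")))
  if (length(all_genes) < signature_size)
    warning("fewer than ", signature_size, " distinct genes; signatures truncated")
  unassigned <- seq_along(robust)
  sets <- top_gene_sets(robust)
  mps <- list()
  while (length(unassigned) > 0) {
    if (length(unassigned) == 1) {
      founder <- unassigned
    } else {
      sumj <- vapply(unassigned, function(i)
        sum(vapply(unassigned, function(j)
          if (i == j) 0 else jaccard(sets[[i]], sets[[j]]), numeric(1))),
        numeric(1))
      founder <- unassigned[order(-sumj, unassigned)[1]]
    }
    members_idx <- founder
    unassigned <- setdiff(unassigned, founder)
    sig <- mp_signature(robust[members_idx], signature_size)
    repeat {
      if (length(unassigned) == 0) break
      ov <- vapply(unassigned, function(j) length(intersect(sets[[j]], sig)), integer(1))
      best <- order(-ov, unassigned)[1]
      if (ov[best] < min_join_overlap) break
      members_idx <- c(members_idx, unassigned[best])
      unassigned <- unassigned[-best]
      sig <- mp_signature(robust[members_idx], signature_size)
    }
    mem <- robust[members_idx]
    mps[[length(mps) + 1]] <- list(
      members = mem, signature = sig,
      member_samples = sort(unique(vapply(mem, `[[`, character(1), "sample_id"))))
  }
  mps <- Filter(function(mp) length(mp$member_samples) >= 2, mps)
  for (i in seq_along(mps)) mps[[i]]$mp_id <- paste0("MP", i)
  mps
}

#' Functional annotation of a meta-program signature
#'
#' Hypergeometric over-representation of the signature in each gene set:
#' `p = P(X >= overlap)` with `X ~ Hypergeometric(universe_size, set size,
#' signature size)`, plus Benjamini-Hochberg adjustment across sets.
#'
#' @param mp a `MetaProgram` (or any list with a `signature` field).
#' @param sets named list of gene sets (e.g. from [read_gmt]).
#' @param universe_size number of genes in the testable universe.
#' @param universe optional explicit universe of gene ids; set members and
#'   signature genes outside it are dropped with a warning.
#' @return data.frame with set_name, set_size, overlap, p_value, p_adjusted.
#' @export
annotate_mp <- function(mp, sets, universe_size, universe = NULL) {
  sig <- mp$signature
  if (!is.null(universe)) {
    out_of_universe <- setdiff(unique(c(sig, unlist(sets))), universe)
    if (length(out_of_universe) > 0)
      warning(length(out_of_universe), " gene id(s) outside universe dropped")
    sig <- intersect(sig, universe)
    sets <- lapply(sets, intersect, universe)
  }
  if (universe_size < max(lengths(sets)))
    stop("universe_size smaller than the largest gene set")
  rows <- lapply(names(sets), function(nm) {
    s <- unique(sets[[nm]])
    ov <- length(intersect(sig, s))
    p <- stats::phyper(ov - 1, length(s), universe_size - length(s),
                       length(sig), lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(s), overlap = ov,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$set_name), , drop = FALSE]
}
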