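test_that("jaccard index: bounds, symmetry, worked value", {
  expect_identical(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_identical(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_identical(jaccard(character(0), character(0)), 0)
  a <- sprintf("g%02d", 1:30); b <- sprintf("g%02d", 21:50)
  expect_equal(jaccard(a, b), 10 / 50)   # |I|=10, |U|=50
  set.seed(4)
  for (i in 1:20) {
    x <- sample(letters, sample(1:10, 1)); y <- sample(letters, sample(1:10, 1))
    j <- jaccard(x, y)
    expect_identical(j, jaccard(y, x))
    expect_true(j >= 0 && j <= 1)
    expect_identical(j == 1, setequal(x, y))
  }
})

test_that("consensus NMF separates disjoint gene blocks at k = 2", {
  set.seed(31)
  G <- 40; N <- 60
  X <- matrix(0.01, G, N)
  cellgrp <- rep(1:2, each = N / 2)
  X[1:20, cellgrp == 1] <- X[1:20, cellgrp == 1] + 5 + runif(20 * N / 2)
  X[21:40, cellgrp == 2] <- X[21:40, cellgrp == 2] + 5 + runif(20 * N / 2)
  rownames(X) <- sprintf("g%02d", 1:G)
  res <- consensus_nmf(X, k = 2, n_replicates = 6, seed = 9, top_genes = 10)
  blocks <- list(sprintf("g%02d", 1:20), sprintf("g%02d", 21:40))
  for (p in res$programs) {
    inside <- vapply(blocks, function(b) sum(p$top_genes %in% b), numeric(1))
    expect_identical(max(inside), 10)   # top genes entirely within one block
  }
  # both blocks are represented
  tops <- vapply(res$programs, function(p) which.max(
    vapply(blocks, function(b) sum(p$top_genes %in% b), numeric(1))), numeric(1))
  expect_setequal(tops, c(1, 2))
})

test_that("consensus NMF recovers an exact rank-1 matrix", {
  set.seed(5)
  w <- runif(25, 0.5, 2); h <- runif(30, 0.5, 2)
  X <- outer(w, h)
  res <- consensus_nmf(X, k = 1, n_replicates = 4, seed = 2, max_iter = 2000,
                       tol = 1e-10)
  expect_lt(res$error, 1e-6 * norm(X, "F"))
})

test_that("consensus NMF is deterministic and beats the worst replicate", {
  set.seed(17)
  X <- matrix(rpois(35 * 40, 3), 35, 40) + 0.0
  a <- consensus_nmf(X, k = 3, n_replicates = 5, seed = 11, max_iter = 3000,
                     tol = 1e-7)
  b <- consensus_nmf(X, k = 3, n_replicates = 5, seed = 11, max_iter = 3000,
                     tol = 1e-7)
  expect_identical(a$programs, b$programs)
  expect_identical(a$usage, b$usage)
  # within the solver's convergence tolerance
  expect_lte(a$error, a$worst_replicate_error * (1 + 1e-3))
  # errors and usages are finite and nonnegative
  expect_true(all(a$usage >= 0))
  expect_true(all(vapply(a$programs, function(p) all(p$spectrum >= 0), logical(1))))
})

test_that("consensus NMF rejects infeasible ranks", {
  X <- matrix(runif(20), 4, 5)
  expect_error(consensus_nmf(X, k = 4, n_replicates = 2), "k must be <")
})

test_that("programs_for_sample concatenates ranks with provenance", {
  m <- rand_cm(40, 50, seed = 23, lambda = 3)
  cfg <- program_set_config(k_min = 2, k_max = 3, n_replicates = 2, seed = 3)
  progs <- programs_for_sample(m, cfg, sample_id = "S1")
  expect_length(progs, 5)   # 2 + 3
  expect_identical(vapply(progs, `[[`, numeric(1), "k"), c(2, 2, 3, 3, 3))
  expect_identical(unique(vapply(progs, `[[`, character(1), "sample_id")), "S1")
  idx <- vapply(progs, `[[`, numeric(1), "program_index")
  expect_identical(idx, c(1, 2, 1, 2, 3))
})

test_that("select_robust applies both overlap criteria", {
  pool <- sprintf("p%02d", 1:50)
  # program A1 (S1,k=4) shares 40 genes with A2 (S1,k=5) and 15 with B1 (S2,k=4)
  a1 <- make_program("S1", 4, 1, c(pool[1:40], sprintf("a1_%02d", 1:10)))
  a2 <- make_program("S1", 5, 1, c(pool[1:40], sprintf("a2_%02d", 1:10)))
  b1 <- make_program("S2", 4, 1, c(pool[26:40], sprintf("b1_%02d", 1:35)))
  # c1 has intra support only; d1 has inter support only
  c1 <- make_program("S1", 4, 2, c(sprintf("cc_%02d", 1:40), sprintf("c1_%02d", 1:10)))
  c2 <- make_program("S1", 5, 2, c(sprintf("cc_%02d", 1:40), sprintf("c2_%02d", 1:10)))
  d1 <- make_program("S2", 5, 1, c(pool[1:15], sprintf("d1_%02d", 1:35)))
  progs <- list(a1, a2, b1, c1, c2, d1)
  kept <- select_robust(progs, intra_overlap_min = 35, inter_overlap_min = 10)
  kept_ids <- vapply(kept, function(p) paste(p$sample_id, p$k, p$program_index), character(1))
  expect_setequal(kept_ids, c("S1 4 1", "S1 5 1"))

  # brute-force oracle over all pairs agrees
  oracle <- function(progs, intra, inter) {
    keep <- logical(length(progs))
    for (i in seq_along(progs)) {
      ia <- FALSE; ib <- FALSE
      for (j in seq_along(progs)) {
        if (i == j) next
        ov <- length(intersect(progs[[i]]$top_genes, progs[[j]]$top_genes))
        same_s <- progs[[i]]$sample_id == progs[[j]]$sample_id
        if (same_s && progs[[i]]$k != progs[[j]]$k && ov >= intra) ia <- TRUE
        if (!same_s && ov >= inter) ib <- TRUE
      }
      keep[i] <- ia && ib
    }
    progs[keep]
  }
  for (th in list(c(35, 10), c(20, 5), c(41, 16))) {
    expect_identical(select_robust(progs, th[1], th[2]), oracle(progs, th[1], th[2]))
  }
})

test_that("select_robust degenerate inputs: one sample or one K", {
  p1 <- make_program("S1", 4, 1, sprintf("x%02d", 1:50))
  p2 <- make_program("S1", 5, 1, sprintf("x%02d", 1:50))
  expect_warning(out <- select_robust(list(p1, p2)), "one sample")
  expect_length(out, 0)
  # two samples but a single K each: intra criterion unsatisfiable
  q1 <- make_program("S1", 4, 1, sprintf("x%02d", 1:50))
  q2 <- make_program("S2", 4, 1, sprintf("x%02d", 1:50))
  expect_length(select_robust(list(q1, q2)), 0)
})

test_that("select_robust is monotone in evidence and returns a subset", {
  pool <- sprintf("m%02d", 1:50)
  p1 <- make_program("S1", 4, 1, pool)
  p2 <- make_program("S1", 5, 1, pool)
  p3 <- make_program("S2", 4, 1, c(pool[1:12], sprintf("q%02d", 1:38)))
  p4 <- make_program("S2", 5, 1, c(pool[1:12], sprintf("q%02d", 1:38)))
  base <- list(p1, p2, p3, p4)
  kept <- select_robust(base)
  expect_true(all(vapply(kept, function(p) any(vapply(base, identical, logical(1), p)),
                         logical(1))))
  # adding a duplicate of a retained program never removes it
  kept2 <- select_robust(c(base, list(p1)))
  ids <- function(l) vapply(l, function(p) paste(p$sample_id, p$k, p$program_index),
                            character(1))
  expect_true(all(ids(kept) %in% ids(kept2)))
})

test_that("meta-program clustering recovers a planted partition", {
  set.seed(41)
  pools <- list(sprintf("A%02d", 1:45), sprintf("B%02d", 1:45), sprintf("C%02d", 1:45))
  robust <- list()
  for (g in 1:3) {
    robust <- c(robust, planted_program_family(pools[[g]], 4,
                                               samples = c("S1", "S2"),
                                               k_values = c(4, 5), seed = g,
                                               index_offset = 10 * g))
  }
  mps <- cluster_metaprograms(robust, min_join_overlap = 10, signature_size = 30)
  expect_length(mps, 3)
  for (mp in mps) {
    expect_length(mp$signature, 30)
    expect_gte(length(mp$member_samples), 2)
    best <- max(vapply(pools, function(p) jaccard(mp$signature, p), numeric(1)))
    expect_gte(best, 0.5)
  }
  # members partition the robust set: no program in two MPs
  all_members <- unlist(lapply(mps, function(mp) vapply(
    mp$members, function(p) paste(p$sample_id, p$k, p$program_index), character(1))))
  expect_identical(anyDuplicated(all_members), 0L)
})

test_that("single-sample meta-programs are discarded", {
  solo <- planted_program_family(sprintf("Z%02d", 1:45), 4,
                                 samples = "S9", k_values = c(4, 5), seed = 8)
  multi <- planted_program_family(sprintf("W%02d", 1:45), 4,
                                  samples = c("S1", "S2"), k_values = c(4, 5),
                                  seed = 9)
  mps <- cluster_metaprograms(c(solo, multi), min_join_overlap = 10)
  expect_length(mps, 1)
  expect_gte(length(mps[[1]]$member_samples), 2)
  expect_gte(jaccard(mps[[1]]$signature, sprintf("W%02d", 1:45)), 0.5)
})

test_that("signatures are truncated with a warning when genes run short", {
  p1 <- make_program("S1", 4, 1, sprintf("t%02d", 1:20))
  p2 <- make_program("S2", 5, 1, sprintf("t%02d", 1:20))
  expect_warning(mps <- cluster_metaprograms(list(p1, p2), min_join_overlap = 5),
                 "truncated")
  expect_length(mps[[1]]$signature, 20)
})

test_that("hypergeometric annotation matches exact enumeration", {
  # universe 10, set of 5, signature of 3, overlap 3: p = C(5,3)/C(10,3)
  mp <- list(signature = c("A", "B", "C"))
  sets <- list(S = c("A", "B", "C", "D", "E"))
  res <- annotate_mp(mp, sets, universe_size = 10)
  expect_equal(res$p_value, choose(5, 3) / choose(10, 3))
  expect_equal(res$p_value, 10 / 120, tolerance = 1e-12)

  # overlap 0 -> P(X >= 0) = 1; signature subset of set = universe -> p = 1
  res0 <- annotate_mp(list(signature = c("A", "B")), list(S = c("X", "Y")),
                      universe_size = 10)
  expect_identical(res0$p_value, 1)
  resU <- annotate_mp(list(signature = c("A", "B")),
                      list(S = c("A", "B", "C")), universe_size = 3)
  expect_equal(resU$p_value, 1)

  # BH adjustment column present and ordered with p
  multi <- annotate_mp(mp, list(S1 = c("A", "B", "C", "D", "E"),
                                S2 = c("F", "G")), universe_size = 10)
  expect_true(all(multi$p_adjusted >= multi$p_value - 1e-15))
  # out-of-universe members are dropped with a warning
  expect_warning(annotate_mp(mp, list(S = c("A", "ZZZ")), universe_size = 5,
                             universe = c("A", "B", "C", "D", "E")),
                 "outside universe")
})
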