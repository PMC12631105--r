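test_that("module score is zero on a constant matrix", {
  m <- make_cm(matrix(3L, 30, 10))
  s <- module_score(m, gene_ids(m)[1:5], n_bins = 4, n_ctrl = 10, seed = 2)
  expect_equal(unname(s), rep(0, 10), tolerance = 1e-12)
})

test_that("module score equals an independent enumeration of the seeded draw", {
  set.seed(77)
  counts <- matrix(rpois(40 * 8, 4), 40, 8)
  m <- make_cm(counts)
  n_bins <- 2; n_ctrl <- 5; seed <- 123
  sig <- gene_ids(m)[c(3, 17)]
  got <- module_score(m, sig, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)

  # independent recomputation following the documented procedure
  expr <- as.matrix(lognorm(m))
  means <- rowMeans(expr)
  G <- nrow(expr)
  rk <- rank(means, ties.method = "min")
  bin <- floor((rk - 1) * n_bins / G) + 1
  names(bin) <- rownames(expr)
  set.seed(seed)
  ctrl <- unlist(lapply(sig, function(g) {
    pool <- names(bin)[bin == bin[[g]]]
    if (length(pool) >= n_ctrl) sample(pool, n_ctrl) else sample(pool, n_ctrl, TRUE)
  }))
  want <- colMeans(expr[sig, , drop = FALSE]) - colMeans(expr[ctrl, , drop = FALSE])
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("module score responds to signature perturbation and errors on empty signature", {
  set.seed(9)
  counts <- matrix(rpois(50 * 6, 3), 50, 6)
  counts[1:8, 1] <- counts[1:8, 1] * 4 + 8   # boost signature genes in cell 1
  m <- make_cm(counts)
  s <- module_score(m, gene_ids(m)[1:8], seed = 5)
  expect_gt(s[1], max(s[-1]))
  expect_warning(s2 <- module_score(m, c(gene_ids(m)[1:3], "ABSENT"), seed = 5),
                 "absent")
  expect_error(suppressWarnings(module_score(m, c("NOPE1", "NOPE2"))),
               "empty signature")
})

test_that("random-signature module scores center on zero under the null", {
  m <- rand_cm(120, 40, seed = 55, lambda = 3)
  set.seed(99)
  means <- replicate(100, {
    sig <- sample(gene_ids(m), 8)
    mean(module_score(m, sig, seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(means)), 0.05)
})

test_that("rank-AUC hits its extremes", {
  # one cell; 20 genes with strictly decreasing counts
  counts <- matrix(20:1, 20, 1)
  m <- make_cm(counts)
  top <- gene_ids(m)[1:3]      # the top-ranked genes
  bottom <- gene_ids(m)[16:20] # entirely outside the top 25%
  expect_equal(unname(rank_auc(m, top, top_fraction = 0.25)), 1)
  expect_equal(unname(rank_auc(m, bottom, top_fraction = 0.25)), 0)
  expect_error(rank_auc(m, "ABSENT"), "disjoint")
  expect_error(rank_auc(m, top, top_fraction = 0), "top_fraction")
})

test_that("rank-AUC matches brute-force recovery-curve integration", {
  # G = 10, top_fraction 0.5 -> threshold 5; set at ranks 1 and 3
  counts <- matrix(c(100, 5, 90, 4, 3, 80, 2, 1, 70, 60), 10, 1)
  m <- make_cm(counts)
  # ranks: g01=1, g03=2, g06=3, g09=4, g10=5, ...
  gset <- c("g001", "g006")   # ranks 1 and 3
  got <- unname(rank_auc(m, gset, top_fraction = 0.5))
  # brute force: step curve hits(t) over t = 1..5
  pos <- c(1, 3); thresh <- 5
  hits <- vapply(1:thresh, function(t) sum(pos <= t), numeric(1))
  s <- min(length(pos), thresh)
  max_area <- sum(vapply(1:thresh, function(t) min(t, s), numeric(1)))
  expect_equal(got, sum(hits) / max_area, tolerance = 1e-12)
  expect_equal(got, 8 / 9, tolerance = 1e-12)
})

test_that("rank-AUC is invariant under monotone transforms of expression", {
  set.seed(3)
  counts <- matrix(rpois(60 * 15, 5), 60, 15)
  m1 <- make_cm(counts)
  m2 <- make_cm(counts^2)           # strictly monotone on nonnegative ints
  gset <- gene_ids(m1)[sample(60, 7)]
  expect_equal(rank_auc(m1, gset, top_fraction = 0.2, seed = 4),
               rank_auc(m2, gset, top_fraction = 0.2, seed = 4))
})

test_that("pseudobulk sums counts per group and conserves totals", {
  counts <- matrix(1:12, 3, 4)
  m <- make_cm(counts, sample = c("A", "A", "B", "B"))
  pb <- pseudobulk(m)
  expect_equal(unname(pb[, "A"]), unname(rowSums(counts[, 1:2])))
  expect_equal(unname(pb[, "B"]), unname(rowSums(counts[, 3:4])))
  expect_equal(sum(pb), sum(counts))
  # one cell per group: pseudobulk equals the cell profile
  m1 <- make_cm(counts, sample = paste0("S", 1:4))
  expect_equal(unname(pseudobulk(m1)), unname(counts))
  expect_error(pseudobulk(m, by = "nope"), "unknown grouping column")
})

test_that("luminal/basal call compares scores with tie handling", {
  res <- call_luminal_basal(c(S1 = 0.4, S2 = 0.1, S3 = 0.2),
                            c(S1 = 0.1, S2 = 0.4, S3 = 0.2))
  expect_identical(res$label, c("basal", "luminal", "indeterminate"))
  expect_equal(res$margin, c(0.3, -0.3, 0))
  expect_error(call_luminal_basal(c(S1 = 1), c(S2 = 1)), "same samples")
})

test_that("samples with a planted subtype program get the matching call", {
  basal_idx <- 30:49; luminal_idx <- 60:79
  one_sample <- function(planted_idx, group, seed) {
    cfg <- cohort_config(n_samples = 1, cells_per_sample = 150, n_genes = 200,
                         n_celltypes = 1, group_labels = group,
                         planted_programs = list(
                           list(genes = planted_idx, frac = 1.0, logfc = 3)),
                         seed = seed)
    generate_cohort(cfg)$matrix
  }
  score_sample <- function(m, sample_name) {
    basal_set <- gene_ids(m)[basal_idx]; luminal_set <- gene_ids(m)[luminal_idx]
    c(basal = mean(rank_auc(m, basal_set, top_fraction = 0.25)),
      luminal = mean(rank_auc(m, luminal_set, top_fraction = 0.25)))
  }
  sb <- score_sample(one_sample(basal_idx, "MI-basal", 61))
  sl <- score_sample(one_sample(luminal_idx, "MI-luminal", 62))
  res <- call_luminal_basal(c(B = sb[["basal"]], L = sl[["basal"]]),
                            c(B = sb[["luminal"]], L = sl[["luminal"]]))
  expect_identical(res$label[res$sample == "B"], "basal")
  expect_identical(res$label[res$sample == "L"], "luminal")
})

test_that("the four-gene gate requires detectable expression of all genes", {
  gate <- c("HLA-DRA", "HLA-DRB1", "HLA-DPA1", "HLA-DPB1")
  counts <- cbind(c(1, 2, 3, 4, 0), c(1, 0, 3, 4, 2), c(0, 0, 0, 0, 0),
                  c(9, 9, 9, 9, 9), c(1, 1, 1, 1, 0), c(0, 1, 1, 1, 5))
  m <- make_cm(counts, genes = c(gate, "OTHER"), sample = rep("S1", 6))
  res <- mhc2_gate(m)
  expect_identical(unname(res$positive), c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(res$fraction_by_sample$fraction, 3 / 6)
  expect_error(mhc2_gate(subset_cm(m, genes = 2:5)),
               "HLA-DRA")
})

test_that("the gate is monotone: raising a count never loses positivity", {
  gate <- c("HLA-DRA", "HLA-DRB1", "HLA-DPA1", "HLA-DPB1")
  set.seed(8)
  counts <- matrix(rpois(5 * 30, 0.8), 5, 30)
  m <- make_cm(counts, genes = c(gate, "OTHER"), sample = rep("S1", 30))
  before <- mhc2_gate(m)$positive
  bumped <- counts; bumped[cbind(sample(1:5, 30, TRUE), 1:30)] <-
    bumped[cbind(sample(1:5, 30, TRUE), 1:30)] + 3L
  after <- mhc2_gate(make_cm(bumped, genes = c(gate, "OTHER"),
                             sample = rep("S1", 30)))$positive
  expect_true(all(after[before]))
})
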