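---
title: "metaniche: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaniche: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
what each statistic assumes, which parameters matter and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# Scope and data model

The package covers the downstream statistics of a single-cell / spatial
study of urothelial carcinoma progression: quality control, consensus-NMF
meta-program discovery in malignant cells, signature scoring and the
four-gene MHC-II gate, observed/expected (Ro/e) cell-type enrichment, and
spatial colocalization of deconvolved cell-type abundances. Upstream steps
that established tools already own — read mapping, normalization-based
integration, clustering, doublet removal, CNV calling, deconvolution model
training — are out of scope; the package consumes their outputs (count
matrices with per-cell metadata, spot × cell-type abundance tables).

The central container is `CountMatrix`: a sparse genes × cells integer
matrix plus a per-cell metadata table (`sample`, `group`, `tissue`,
`celltype`). Pathology groups follow the cohort structure of the disease:
`Normal`, `NMI` (non-muscle-invasive), and muscle-invasive tumours split
into `MI-luminal` and `MI-basal` molecular subtypes.

# Quality control

`qc_filter()` retains cells with 200–8000 detected genes (count > 0) and at
most 10% mitochondrial counts, the standard single-cell thresholds.
Decisions the thresholds do not pin down:

* *Detection* means count > 0 — the universal convention.
* The gene bounds are **inclusive-retain**: cells with exactly 200 or
  exactly 8000 detected genes pass (the removal rule targets "fewer than
  200 or more than 8000").
* The mitochondrial bound is likewise inclusive: a cell at exactly 10% is
  retained. The fraction is computed on raw counts, before any
  normalization, over genes with the `MT-` name prefix.
* If every cell fails, the result is an empty matrix with a warning, not an
  error — pipelines should be able to report this downstream.

QC commutes with cell permutations and is the identity at thresholds
(0, ∞, 1); both properties are tested.

# Consensus NMF and meta-programs

## Preprocessing

`nmf_preprocess()` applies: mito/ribosomal gene removal (`MT-`, `RPL`,
`RPS` prefixes), counts-per-10k per cell, selection of the top 2000
highly-variable genes (by variance; fewer genes are kept as-is), and
per-gene scaling to unit variance. Scaling is multiplicative — no centering
— so the matrix stays nonnegative as NMF requires. The 2000-gene default
matches the conventional global HVG count used for dimensionality
reduction in this field.

## Consensus factorization

`consensus_nmf(X, k, n_replicates, seed)` runs multiplicative-update
Frobenius NMF (`X ≈ W·H`, both factors ≥ 0) from `n_replicates` random
initializations, then:

1. pools all replicate spectra (columns of `W`), each L2-normalized;
2. drops outlier spectra whose mean distance to their 15 nearest
   neighbours exceeds the 90th percentile (a local-density filter against
   non-reproducible components);
3. k-means-partitions the survivors into `k` clusters and takes the
   per-cluster elementwise **median** as the consensus spectrum;
4. re-fits the usage matrix `H` against the fixed consensus spectra by
   nonnegative least squares (multiplicative updates on `H` only).

Numerical choices: random uniform initialization scaled to the data mean;
500 maximum iterations with a relative-error tolerance of 1e-4 checked
every 10 iterations (tightenable via arguments); the dense inner loop is
implemented in C++ (RcppArmadillo). Programs are ordered by total usage,
and top-gene lists break weight ties lexicographically, so runs are fully
reproducible given the seed. Because the usage-only refit cannot improve
the spectra themselves, the consensus reconstruction error matches the
replicate errors only up to the solver tolerance; the test suite asserts
the "no worse than the worst replicate" property within that tolerance
rather than bitwise.

`programs_for_sample()` sweeps K over 4…12 by default — yielding
`sum(4:12) = 72` programs per sample — with 200 replicates per K (the
production default; tests use 10 to keep runtimes reasonable).

## Robust programs and meta-program clustering

A program is **robust** (`select_robust()`) iff its top-50-gene list
overlaps ≥ 35 genes (70%) with some program of the same sample at a
different K, and ≥ 10 genes (20%) with some program of another sample. The
thresholds follow the published recurrent-program selection scheme this
procedure descends from; since the source does not print its exact values
they are arguments, not constants. With a single sample the cross-sample
criterion is unsatisfiable and the function returns an empty set with a
warning rather than silently relaxing the rule. All samples are pooled for
the cross-sample criterion, including across tissues (upper-tract and
bladder); restricting recurrence to within a tissue would only need a
pre-filter on the program list.

`cluster_metaprograms()` greedily clusters robust programs by gene
overlap: seed with the program with the largest summed Jaccard to all
others; repeatedly add the unassigned program with the largest overlap to
the current signature while that overlap is ≥ `min_join_overlap` (default
10); after each addition recompute the signature as the 30 genes occurring
in the most member top-gene lists (ties by summed spectrum weight, then
gene id); close the cluster when no candidate qualifies and repeat.
Meta-programs whose members all come from one sample are discarded — a
program family private to one tumour is not a meta-program. If fewer than
30 distinct genes exist the signature truncates with a warning.

`annotate_mp()` tests signature/gene-set overlap with the hypergeometric
upper tail, `P(X ≥ overlap)` with population `universe_size`, plus
Benjamini–Hochberg adjustment across sets.

# Scoring and the MHC-II gate

* `module_score()` — the bin-matched control score: genes are placed in 24
  equal-frequency bins of mean log-normalized expression (ties to the
  lower bin); each signature gene draws 100 control genes from its bin
  (without replacement when the bin allows, with replacement otherwise);
  the score is mean(signature) − mean(control multiset) per cell. Control
  draws are pooled as a multiset (duplicates kept) rather than
  deduplicated: it keeps the control average an unbiased bin average and
  the draw logic independent of bin occupancy. On synthetic null data the
  score centers on zero (tested over 100 random signatures).
* `rank_auc()` — per cell, genes are ranked by expression descending; the
  score is the area under the gene set's recovery curve within the top 5%
  of ranks, normalized by the maximal achievable area so it lies in [0, 1].
  Ties are broken by gene order after one seeded shuffle of the gene axis
  fixed per run, so zero-inflated counts do not bias any particular gene
  ordering. The statistic depends only on within-cell ranks and is
  therefore invariant under any strictly monotone transform of expression
  (tested); it is computed on raw counts.
* `call_luminal_basal()` compares per-sample mean rank-AUC of basal vs
  luminal gene sets and reports the margin; exact ties are labeled
  `indeterminate`. This is a score-comparison approximation to
  nearest-centroid molecular subtyping, not a reimplementation of the
  centroid classifier; its behaviour on borderline samples is not
  validated against that tool.
* `mhc2_gate()` — a cell is MHC-II⁺ iff all four gate genes (*HLA-DRA*,
  *HLA-DRB1*, *HLA-DPA1*, *HLA-DPB1*) have expression > 0. Evaluated on
  raw counts; any zero-preserving normalization gives identical calls,
  which is why the layer choice is immaterial. Missing gate genes are an
  error naming the gene. The gate is monotone in counts (tested).

# Ro/e enrichment

`roe()` computes expected counts from the chi-square independence model,
`E[c, g] = n_c· · n_·g / n`, and the ratio observed/expected. Ratios > 1
are labeled enriched, < 1 depleted; exactly 1 — a case the >1/<1 rule does
not cover — is labeled `neutral`. Groups with zero totals yield NA ratios
rather than infinities. No p-value is attached: the ratio itself is the
reported statistic. Margins of the expected table equal the observed
margins and ratios are invariant to uniform count scaling (both tested
against a brute-force oracle).

# Spatial colocalization

Cell-type abundances per spot (from any deconvolution tool) are normalized
to distributions over spots (`to_distribution()`, with pseudocount default
`1e-9 ×` the mean abundance so zero-containing spots keep KL finite) and
compared by symmetric KL divergence `½[KL(p‖q) + KL(q‖p)]` in natural-log
units. Lower divergence means stronger colocalization.

`coloc_permutation()` builds the null exactly as described for this
analysis: each of `n_perm = 1000` rounds draws an independent uniform
subsample of 80% of spots per cell type *without replacement*, restricts
both vectors to the intersection of the two subsampled spot sets,
renormalizes, and recomputes the symmetric KL; the empirical p is the
fraction of null values strictly exceeding the observed one. Two
documented subtleties:

* The subsampling is done verbatim, and it quantifies **subsampling
  stability** of the divergence rather than a classical independence
  null: empirical p hovers near 0.5 for colocalized and independent pairs
  alike, so the observed sKL — not the p — is the discriminating quantity.
  The package reports both and does not reinterpret the procedure.
* Renormalization on the **intersection** of the two subsampled spot sets
  (rather than on each set separately) keeps the two distributions on a
  common support, which symmetric KL requires. Empty intersections are
  redrawn (logged), with a redraw budget equal to `n_perm`.

Because the plain fraction can return an exact 0 (e.g. at `frac = 1`,
where every null value equals the observed), the add-one estimator
`(b + 1)/(n + 1)` is available behind `add_one = TRUE`.

`compartment_nmf()` factorizes the spot × cell-type abundance matrix into
nonnegative co-occurrence compartments (5 restarts, best fit kept,
seeded); per-factor cell-type weights are also returned scaled to max 1
for display.

# Synthetic data: what it emulates, what it does not

`generate_cohort()` draws negative-binomial counts with
`var = mu + alpha·mu²` around per-gene baseline means (gamma-distributed),
modified by: a 5× identity block per cell type (disjoint gene blocks), the
planted activity programs (means multiplied by `2^logfc` in member cells),
per-group planted MHC-II⁺ cells (8× elevated gate-gene means and
guaranteed > 0 counts on all four gate genes), and per-cell log-normal
size factors (sdlog 0.3) that make library-size normalization matter.
Mito/ribo tag genes carry the conventional name prefixes so QC behaves as
on real data. One global seed drives a per-sample seed sequence, so
cohorts are reproducible sample by sample.

Default study conditions: four pathology groups cycling across samples;
MHC-II⁺ fractions 0 / 0.02 / 0.05 / 0.2 for Normal / NMI / MI-luminal /
MI-basal — a gradient peaking around 20% in MI-basal tumours, the regime
the gate is meant to resolve; dispersion alpha 0.5 (size 2), a typical
droplet-data overdispersion; planted activity programs default to log2
fold 2.0 in 30% of cells, an effect size chosen for testability since no
published effect-size range exists for meta-program activation.

The generator deliberately does **not** simulate ambient RNA, doublets,
batch effects, gene–gene correlation beyond the planted programs, or
spatial transcript counts (spot abundances are generated directly as
background + shared Gaussian niche bumps + truncated noise). Passing tests
therefore demonstrate correctness of the statistics under a clean
generative model, not robustness to those artifacts.

# Problem sizes in the test suite

The suite exercises the full pipeline at deliberately small scales chosen
as the package's own test conditions: the rank-sweep check runs one
200-cell × 500-gene sample at 10 replicates; planted-program recovery uses
3-sample cohorts of 150 cells × 300 genes over 20 seeds (3 planted 40-gene
programs, log2 fold 2.0, 30% membership), requiring each planted set to be
recovered by some meta-program at Jaccard ≥ 0.5 in ≥ 90% of seeds (with a
30-gene signature against a 40-gene planted set the maximum attainable
Jaccard is 0.75); gate recovery compares MI-basal fractions against the
planted 0.2 plus a chance-positive component estimated from Normal
samples, using binomial 95% intervals over 20 seeds; colocalization uses
20 × 20 grids with 200 permutations at three niche strengths. Production
defaults (200 replicates, 1000 permutations) remain the config defaults.

# Known limitations

* The NMF rank K is swept, never selected; meta-programs aggregate over
  the sweep by design, so no per-sample "best K" is reported.
* Robustness thresholds (35/10 of top-50) are convention-derived defaults,
  not estimated from data; sensitivity to them should be explored per
  dataset via the exposed arguments.
* The luminal/basal call is a score comparison, not the centroid
  classifier (see above).
* The colocalization p-value inherits the subsampling-null caveat above;
  treat observed sKL orderings, not p thresholds, as the primary readout.
* Ro/e is reported without a significance measure, as the statistic is
  conventionally used descriptively.
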