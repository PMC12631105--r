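#' Configure a synthetic multi-sample single-cell cohort
#'
#' Describes a cohort of urothelial-carcinoma-like samples to simulate:
#' negative-binomial counts with per-cell-type identity programs, optional
#' planted activity programs (gene sets switched on in a fraction of cells at
#' a given log2 fold change), and a planted MHC-II-positive cell fraction per
#' pathology group. Mitochondrial and ribosomal genes are appended at the end
#' of the gene axis with the conventional "MT-"/"RPL"/"RPS" name prefixes so
#' the QC stage can recognize them.
#'
#' @param n_samples number of samples.
#' @param cells_per_sample cells simulated per sample.
#' @param n_genes total genes, including mito/ribo tag genes.
#' @param n_celltypes number of cell types; type 1 plays the malignant
#'   epithelial compartment.
#' @param planted_programs list of activity programs, each a list with
#'   `genes` (integer gene indices), `frac` (active cell fraction in `[0,1]`)
#'   and `logfc` (log2 fold activation of the program genes in member cells).
#' @param group_labels character vector, one pathology group per sample, from
#'   `c("Normal","NMI","MI-luminal","MI-basal")`. Defaults to cycling through
#'   the four groups.
#' @param tissue_labels per-sample tissue labels (default alternates
#'   UTUC/UCB).
#' @param mito_gene_count,ribo_gene_count number of "MT-"/ribosomal tag genes
#'   (taken from the end of the gene axis).
#' @param nb_dispersion negative-binomial dispersion alpha, so that
#'   `var = mu + alpha * mu^2`.
#' @param mhc2_gene_indices exactly 4 distinct gene indices acting as the
#'   HLA-DRA/HLA-DRB1/HLA-DPA1/HLA-DPB1 gate genes.
#' @param mhc2_positive_fraction_by_group named numeric vector mapping each
#'   group to the fraction of its cells planted as MHC-II positive. The
#'   default puts 20% positives in MI-basal samples, a small fraction in
#'   MI-luminal, and near none elsewhere, mirroring the gradient reported for
#'   muscle-invasive basal tumours.
#' @param base_mean_shape,base_mean_rate gamma hyperparameters for per-gene
#'   baseline means.
#' @param libsize_sdlog per-cell log-normal size-factor sd (mean 0 on the log
#'   scale).
#' @param seed integer seed; one global seed drives a per-sample seed
#'   sequence so each sample is independently reproducible.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_samples = 4,
                          cells_per_sample = 300,
                          n_genes = 600,
                          n_celltypes = 3,
                          planted_programs = list(),
                          group_labels = NULL,
                          tissue_labels = NULL,
                          mito_gene_count = 10,
                          ribo_gene_count = 20,
                          nb_dispersion = 0.5,
                          mhc2_gene_indices = NULL,
                          mhc2_positive_fraction_by_group = c(
                            "Normal" = 0.0, "NMI" = 0.02,
                            "MI-luminal" = 0.05, "MI-basal" = 0.2),
                          base_mean_shape = 0.4,
                          base_mean_rate = 0.25,
                          libsize_sdlog = 0.3,
                          seed = 1L) {
  groups <- c("Normal", "NMI", "MI-luminal", "MI-basal")
  if (is.null(group_labels))
    group_labels <- rep(groups, length.out = n_samples)
  if (is.null(tissue_labels))
    tissue_labels <- rep(c("UTUC", "UCB"), length.out = n_samples)
  if (is.null(mhc2_gene_indices)) {
    n_plain <- n_genes - mito_gene_count - ribo_gene_count
    mhc2_gene_indices <- seq(max(1, n_plain - 3), length.out = 4)
  }
  cfg <- list(n_samples = as.integer(n_samples),
              cells_per_sample = as.integer(cells_per_sample),
              n_genes = as.integer(n_genes),
              n_celltypes = as.integer(n_celltypes),
              planted_programs = planted_programs,
              group_labels = group_labels,
              tissue_labels = tissue_labels,
              mito_gene_count = as.integer(mito_gene_count),
              ribo_gene_count = as.integer(ribo_gene_count),
              nb_dispersion = nb_dispersion,
              mhc2_gene_indices = as.integer(mhc2_gene_indices),
              mhc2_positive_fraction_by_group = mhc2_positive_fraction_by_group,
              base_mean_shape = base_mean_shape,
              base_mean_rate = base_mean_rate,
              libsize_sdlog = libsize_sdlog,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_samples < 1 || cfg$cells_per_sample < 1 || cfg$n_genes < 1)
    stop("configuration error: zero samples, cells or genes")
  if (cfg$n_celltypes < 1) stop("configuration error: n_celltypes < 1")
  if (cfg$nb_dispersion <= 0) stop("configuration error: nb_dispersion must be > 0")
  if (length(cfg$group_labels) != cfg$n_samples)
    stop("configuration error: group_labels length != n_samples")
  if (!all(cfg$group_labels %in% c("Normal", "NMI", "MI-luminal", "MI-basal")))
    stop("configuration error: unknown group label")
  if (length(unique(cfg$mhc2_gene_indices)) != 4)
    stop("configuration error: mhc2_gene_indices must be 4 distinct indices")
  if (any(cfg$mhc2_gene_indices < 1 | cfg$mhc2_gene_indices > cfg$n_genes))
    stop("configuration error: mhc2_gene_indices out of gene range")
  fr <- cfg$mhc2_positive_fraction_by_group
  if (any(fr < 0 | fr > 1)) stop("configuration error: fractions must be in [0,1]")
  for (pp in cfg$planted_programs) {
    if (is.null(pp$genes) || is.null(pp$frac) || is.null(pp$logfc))
      stop("configuration error: planted program needs genes, frac, logfc")
    if (any(pp$genes < 1 | pp$genes > cfg$n_genes))
      stop("configuration error: planted gene set exceeds gene range")
    if (pp$frac < 0 || pp$frac > 1)
      stop("configuration error: program fraction must be in [0,1]")
  }
  invisible(cfg)
}

synth_gene_names <- function(cfg) {
  n_plain <- cfg$n_genes - cfg$mito_gene_count - cfg$ribo_gene_count
  if (n_plain < 0) stop("configuration error: mito+ribo genes exceed n_genes")
  n_rpl <- ceiling(cfg$ribo_gene_count / 2)
  c(sprintf("G%04d", seq_len(n_plain)),
    if (cfg$mito_gene_count > 0) paste0("MT-", seq_len(cfg$mito_gene_count)),
    if (n_rpl > 0) paste0("RPL", seq_len(n_rpl)),
    if (cfg$ribo_gene_count - n_rpl > 0) paste0("RPS", seq_len(cfg$ribo_gene_count - n_rpl)))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Counts are negative binomial around `mu = base_mean * celltype_mult *
#' program_mult * size_factor`. Each cell type owns a disjoint identity gene
#' block (5x elevated); planted activity programs multiply their genes'
#' means by `2^logfc` in member cells; cells planted as MHC-II positive get
#' elevated means on the four gate genes and are guaranteed strictly
#' positive counts there. Identical seed gives bitwise-identical output.
#'
#' @param cfg a [cohort_config].
#' @return list with `matrix` (a [CountMatrix]) and `truth`, a list holding
#'   `program_membership` (cells x programs logical matrix),
#'   `mhc2_positive` (logical per cell), and `celltype` (per cell).
#' @export
generate_cohort <- function(cfg) {
  validate_cohort_config(cfg)
  gnames <- synth_gene_names(cfg)
  G <- cfg$n_genes
  set.seed(cfg$seed)
  base_mean <- stats::rgamma(G, shape = cfg$base_mean_shape, rate = cfg$base_mean_rate) + 0.02
  # disjoint identity blocks over the non-tagged genes, one per cell type
  n_plain <- G - cfg$mito_gene_count - cfg$ribo_gene_count
  block <- floor(n_plain / (2 * cfg$n_celltypes))
  identity_sets <- lapply(seq_len(cfg$n_celltypes), function(t)
    seq((t - 1) * block + 1, length.out = block))
  sample_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_samples)

  n_prog <- length(cfg$planted_programs)
  counts_list <- vector("list", cfg$n_samples)
  meta_list <- vector("list", cfg$n_samples)
  memb_list <- vector("list", cfg$n_samples)
  mhc2_list <- vector("list", cfg$n_samples)
  size_nb <- 1 / cfg$nb_dispersion

  for (s in seq_len(cfg$n_samples)) {
    set.seed(sample_seeds[s])
    N <- cfg$cells_per_sample
    ct <- sample.int(cfg$n_celltypes, N, replace = TRUE)
    sf <- stats::rlnorm(N, 0, cfg$libsize_sdlog)
    mu <- matrix(base_mean, nrow = G, ncol = N)
    for (t in seq_len(cfg$n_celltypes))
      mu[identity_sets[[t]], ct == t] <- mu[identity_sets[[t]], ct == t] * 5

    memb <- matrix(FALSE, nrow = N, ncol = max(1, n_prog))
    for (p in seq_len(n_prog)) {
      pp <- cfg$planted_programs[[p]]
      members <- sample.int(N, round(pp$frac * N))
      memb[members, p] <- TRUE
      if (length(members) > 0)
        mu[pp$genes, members] <- mu[pp$genes, members] * 2^pp$logfc
    }

    grp <- cfg$group_labels[s]
    pos_frac <- cfg$mhc2_positive_fraction_by_group[[grp]]
    if (is.null(pos_frac) || is.na(pos_frac)) pos_frac <- 0
    mhc2_pos <- rep(FALSE, N)
    if (pos_frac > 0) {
      pos <- sample.int(N, round(pos_frac * N))
      mhc2_pos[pos] <- TRUE
      mu[cfg$mhc2_gene_indices, pos] <- pmax(mu[cfg$mhc2_gene_indices, pos] * 8, 2)
    }

    mu <- sweep(mu, 2, sf, `*`)
    x <- matrix(stats::rnbinom(G * N, mu = as.vector(mu), size = size_nb),
                nrow = G, ncol = N)
    if (any(mhc2_pos))  # the gate guarantee: planted positives never drop out
      x[cfg$mhc2_gene_indices, mhc2_pos] <- pmax(x[cfg$mhc2_gene_indices, mhc2_pos], 1L)

    cid <- sprintf("S%02d_c%04d", s, seq_len(N))
    counts_list[[s]] <- x
    meta_list[[s]] <- data.frame(cell_id = cid,
                                 sample = sprintf("S%02d", s),
                                 group = grp,
                                 tissue = cfg$tissue_labels[s],
                                 celltype = paste0("CT", ct),
                                 stringsAsFactors = FALSE)
    rownames(memb) <- cid
    memb_list[[s]] <- memb
    mhc2_list[[s]] <- mhc2_pos
  }

  counts <- do.call(cbind, counts_list)
  meta <- do.call(rbind, meta_list)
  m <- CountMatrix(counts, gene_ids = gnames, cell_ids = meta$cell_id, cell_meta = meta)
  membership <- do.call(rbind, memb_list)
  if (n_prog > 0) {
    colnames(membership) <- paste0("P", seq_len(n_prog))
  } else membership <- membership[, 0, drop = FALSE]
  truth <- list(program_membership = membership,
                mhc2_positive = stats::setNames(unlist(mhc2_list), meta$cell_id),
                celltype = stats::setNames(meta$celltype, meta$cell_id),
                planted_gene_sets = lapply(cfg$planted_programs,
                                           function(pp) gnames[pp$genes]),
                identity_gene_sets = lapply(identity_sets, function(i) gnames[i]))
  list(matrix = m, truth = truth)
}

#' Configure a synthetic spatial spot grid
#'
#' @param grid_shape integer vector `(rows, cols)`.
#' @param n_celltypes number of cell types with abundance columns.
#' @param niches list of niches, each `list(center = c(row, col), radius,
#'   members = cell-type indices, height = bump height)`; the bump is a
#'   Gaussian in grid distance, shared by all member types of the niche.
#' @param background_intensity positive baseline abundance for every type.
#' @param noise_sd sd of additive Gaussian noise (truncated at zero).
#' @param seed integer seed.
#' @return a validated `spatial_config` list.
#' @export
spatial_config <- function(grid_shape = c(20, 20),
                           n_celltypes = 4,
                           niches = list(),
                           background_intensity = 1,
                           noise_sd = 0.1,
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), n_celltypes = as.integer(n_celltypes),
              niches = niches, background_intensity = background_intensity,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (length(cfg$grid_shape) != 2 || any(cfg$grid_shape < 1))
    stop("configuration error: grid_shape must be two positive integers")
  if (cfg$background_intensity < 0)
    stop("configuration error: background_intensity must be nonnegative")
  if (cfg$noise_sd < 0) stop("configuration error: negative noise_sd")
  for (ni in cfg$niches) {
    if (is.null(ni$center) || is.null(ni$radius) || is.null(ni$members))
      stop("configuration error: niche needs center, radius, members")
    if (ni$center[1] < 1 || ni$center[1] > cfg$grid_shape[1] ||
        ni$center[2] < 1 || ni$center[2] > cfg$grid_shape[2])
      stop("configuration error: niche center outside grid")
    if (any(ni$members < 1 | ni$members > cfg$n_celltypes))
      stop("configuration error: niche member type out of range")
  }
  class(cfg) <- "spatial_config"
  cfg
}

#' Generate a spatial spot-abundance grid with planted niches
#'
#' Abundance of a cell type at a spot is `background + sum of Gaussian niche
#' bumps` over the niches the type belongs to, plus truncated Gaussian noise;
#' all values are nonnegative. Types sharing a niche therefore share a bump
#' and colocalize.
#'
#' @param cfg a [spatial_config].
#' @return list with `abundance` (a data.frame: spot_id, row, col, one column
#'   per cell type `CT1..CTk`) and `truth` (per-spot niche id, 0 = none).
#' @export
generate_spatial <- function(cfg) {
  if (!inherits(cfg, "spatial_config")) cfg <- do.call(spatial_config, cfg)
  set.seed(cfg$seed)
  rows <- cfg$grid_shape[1]; cols <- cfg$grid_shape[2]
  coord <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  n_spot <- nrow(coord)
  ab <- matrix(cfg$background_intensity, nrow = n_spot, ncol = cfg$n_celltypes)
  niche_id <- integer(n_spot)
  for (i in seq_along(cfg$niches)) {
    ni <- cfg$niches[[i]]
    height <- if (is.null(ni$height)) 5 else ni$height
    d2 <- (coord$row - ni$center[1])^2 + (coord$col - ni$center[2])^2
    bump <- height * exp(-d2 / (2 * ni$radius^2))
    for (t in ni$members) ab[, t] <- ab[, t] + bump
    niche_id[d2 <= ni$radius^2 & niche_id == 0] <- i
  }
  if (cfg$noise_sd > 0)
    ab <- pmax(ab + matrix(stats::rnorm(length(ab), 0, cfg$noise_sd),
                           nrow = n_spot), 0)
  out <- data.frame(spot_id = sprintf("spot%04d", seq_len(n_spot)),
                    row = coord$row, col = coord$col, stringsAsFactors = FALSE)
  for (t in seq_len(cfg$n_celltypes)) out[[paste0("CT", t)]] <- ab[, t]
  list(abundance = out, truth = list(niche = stats::setNames(niche_id, out$spot_id)))
}
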