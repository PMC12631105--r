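pipeline_defaults <- function() list(
  out_dir = "metaniche_run",
  seed = 1L,
  # stage toggles
  run_qc = TRUE, run_programs = TRUE, run_mp = TRUE, run_gate = TRUE,
  run_roe = TRUE, run_coloc = TRUE,
  # inputs: either the MTX trio, or synthesize a cohort
  counts_mtx = NULL, genes_tsv = NULL, cells_tsv = NULL,
  synth_cohort = TRUE, n_samples = 3L, cells_per_sample = 200L,
  n_genes = 500L, n_celltypes = 2L, n_planted_programs = 3L,
  planted_logfc = 2.0, planted_frac = 0.3,
  spots_tsv = NULL, synth_spatial = TRUE,
  # QC thresholds
  min_genes = 200L, max_genes = 8000L, max_mito = 0.10,
  # program discovery
  k_min = 4L, k_max = 12L, n_replicates = 200L,
  top_genes_per_program = 50L, n_hvg = 2000L,
  intra_overlap_min = 35L, inter_overlap_min = 10L,
  # meta-programs
  min_join_overlap = 10L, signature_size = 30L,
  # gate
  mhc2_genes = c("HLA-DRA", "HLA-DRB1", "HLA-DPA1", "HLA-DPB1"),
  # Ro/e
  roe_cluster_col = "celltype", roe_group_col = "group",
  # colocalization
  n_perm = 1000L, coloc_frac = 0.8)

#' Validate a pipeline configuration
#'
#' Accepts a flat YAML file path or a named list, applies the package
#' defaults for every unset key (the defaults carry the standard parameter
#' values: rank range 4-12, 200 NMF replicates, 30-gene signatures,
#' 200/8000/10% QC thresholds, 1000 permutations at an 80% subsample), and
#' range-checks the result. All violations are accumulated and reported
#' together.
#'
#' @param config path to a YAML file, a named list, or NULL for pure
#'   defaults.
#' @return the validated, fully-defaulted `run_config` list.
#' @export
validate_config <- function(config = NULL) {
  defaults <- pipeline_defaults()
  user <- if (is.null(config)) list()
          else if (is.character(config)) {
            y <- yaml::read_yaml(config)
            if (is.null(y)) list() else y
          } else as.list(config)
  errors <- character(0)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    errors <- c(errors, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, user[intersect(names(user), names(defaults))])

  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(cfg$k_min >= 2, "k_min must be >= 2")
  chk(cfg$k_min <= cfg$k_max, paste0("ordering error: k_min (", cfg$k_min,
                                     ") > k_max (", cfg$k_max, ")"))
  chk(cfg$n_replicates >= 2, "n_replicates must be >= 2")
  chk(cfg$coloc_frac > 0 && cfg$coloc_frac <= 1,
      paste0("range error: coloc_frac = ", cfg$coloc_frac, " not in (0, 1]"))
  chk(cfg$max_mito >= 0 && cfg$max_mito <= 1,
      paste0("range error: max_mito = ", cfg$max_mito, " not in [0, 1]"))
  chk(cfg$min_genes >= 0 && cfg$min_genes <= cfg$max_genes,
      "QC gene bounds must satisfy 0 <= min_genes <= max_genes")
  chk(cfg$planted_frac >= 0 && cfg$planted_frac <= 1,
      "range error: planted_frac not in [0, 1]")
  chk(length(cfg$mhc2_genes) == 4, "mhc2_genes must list exactly four genes")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$signature_size >= 1, "signature_size must be >= 1")
  if (length(errors) > 0)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

write_tsv_file <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: input (read or synthesize) -> QC ->
#' per-sample consensus-NMF programs -> robust-program selection and
#' meta-program clustering -> MHC-II gate -> Ro/e -> spatial colocalization.
#' Every random choice derives from `config$seed`, and identical
#' config + seed gives byte-identical outputs. Artifacts are written under
#' `config$out_dir`: `mp.json`, `gate.tsv`, `roe.tsv`, `coloc.json`,
#' `skl.tsv` and a `run_report.json` manifest sufficient to re-run
#' identically.
#'
#' @param config a `run_config` from [validate_config], a YAML path, a named
#'   list, or NULL for defaults.
#' @return invisibly, the run report list.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  t0 <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                 stages = list(), warnings = character(0))
  note <- function(stage, ...) {
    report$stages[[stage]] <<- c(report$stages[[stage]], list(...))
  }
  wcatch <- function(expr) withCallingHandlers(expr, warning = function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # ---- input ----
  if (!is.null(cfg$counts_mtx)) {
    if (is.null(cfg$genes_tsv) || is.null(cfg$cells_tsv))
      stop("stage input: counts_mtx given without genes_tsv/cells_tsv")
    m <- read_mtx(cfg$counts_mtx, cfg$genes_tsv, cfg$cells_tsv)
  } else if (isTRUE(cfg$synth_cohort)) {
    planted <- make_default_planted(cfg$n_genes, cfg$n_planted_programs,
                                    cfg$planted_frac, cfg$planted_logfc)
    ccfg <- cohort_config(n_samples = cfg$n_samples,
                          cells_per_sample = cfg$cells_per_sample,
                          n_genes = cfg$n_genes, n_celltypes = cfg$n_celltypes,
                          planted_programs = planted, seed = cfg$seed)
    gen <- generate_cohort(ccfg)
    m <- gen$matrix
    gate_gene_ids <- gene_ids(m)[ccfg$mhc2_gene_indices]
    cfg$mhc2_genes <- gate_gene_ids
  } else stop("stage input: no counts_mtx and synth_cohort disabled")
  note("input", genes = nrow(m$counts), cells = ncol(m$counts))

  # ---- QC ----
  if (isTRUE(cfg$run_qc)) {
    q <- wcatch(qc_filter(m, cfg$min_genes, cfg$max_genes, cfg$max_mito))
    m <- q$matrix
    note("qc", cells_retained = ncol(m$counts),
         thresholds = attr(q$report, "thresholds"))
  }

  # ---- programs & meta-programs ----
  mps <- NULL
  if (isTRUE(cfg$run_programs)) {
    pcfg <- program_set_config(k_min = cfg$k_min, k_max = cfg$k_max,
                               n_replicates = cfg$n_replicates,
                               top_genes_per_program = cfg$top_genes_per_program,
                               n_hvg = cfg$n_hvg, seed = cfg$seed)
    samples <- unique(m$cell_meta$sample)
    programs <- list()
    for (s in samples) {
      ms <- subset_cm(m, cells = which(m$cell_meta$sample == s))
      programs <- c(programs, programs_for_sample(ms, pcfg, sample_id = s))
    }
    note("programs", n_samples = length(samples), n_programs = length(programs))
    if (isTRUE(cfg$run_mp)) {
      robust <- wcatch(select_robust(programs, cfg$intra_overlap_min,
                                     cfg$inter_overlap_min))
      mps <- wcatch(cluster_metaprograms(robust, cfg$min_join_overlap,
                                         cfg$signature_size))
      note("mp", n_robust = length(robust), n_mp = length(mps))
      mp_json <- lapply(mps, function(mp) list(
        mp_id = mp$mp_id, signature = mp$signature,
        member_samples = mp$member_samples,
        members = lapply(mp$members, function(p)
          list(sample_id = p$sample_id, k = p$k, program_index = p$program_index))))
      jsonlite::write_json(mp_json, file.path(cfg$out_dir, "mp.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  } else if (isTRUE(cfg$run_mp)) {
    stop("stage mp: requires the programs stage to be enabled")
  }

  # ---- MHC-II gate ----
  if (isTRUE(cfg$run_gate)) {
    gate <- mhc2_gate(m, cfg$mhc2_genes)
    write_tsv_file(gate$fraction_by_sample, file.path(cfg$out_dir, "gate.tsv"))
    note("gate", genes = gate$genes,
         overall_fraction = mean(gate$positive))
  }

  # ---- Ro/e ----
  if (isTRUE(cfg$run_roe)) {
    rt <- roe_from_meta(m, cfg$roe_cluster_col, cfg$roe_group_col)
    df <- as.data.frame(as.table(rt$ratio), stringsAsFactors = FALSE)
    names(df) <- c("cluster", "group", "roe")
    write_tsv_file(df, file.path(cfg$out_dir, "roe.tsv"))
    note("roe", clusters = nrow(rt$observed), groups = ncol(rt$observed))
  }

  # ---- spatial colocalization ----
  if (isTRUE(cfg$run_coloc)) {
    if (!is.null(cfg$spots_tsv)) {
      a <- read_spot_abundance(cfg$spots_tsv)
    } else if (isTRUE(cfg$synth_spatial)) {
      scfg <- spatial_config(niches = list(
        list(center = c(5, 5), radius = 3, members = c(1, 2)),
        list(center = c(15, 15), radius = 3, members = 3)),
        seed = cfg$seed)
      a <- generate_spatial(scfg)$abundance
    } else stop("stage coloc: no spots_tsv and synth_spatial disabled")
    cp <- coloc_all_pairs(a, n_perm = cfg$n_perm, frac = cfg$coloc_frac,
                          seed = cfg$seed)
    jsonlite::write_json(list(skl = cp$skl, p = cp$p,
                              celltypes = rownames(cp$skl)),
                         file.path(cfg$out_dir, "coloc.json"),
                         matrix = "rowmajor", digits = NA, pretty = TRUE)
    skl_df <- data.frame(celltype = rownames(cp$skl),
                         as.data.frame(cp$skl), check.names = FALSE)
    write_tsv_file(skl_df, file.path(cfg$out_dir, "skl.tsv"))
    note("coloc", n_spots = nrow(a), n_types = ncol(cp$skl),
         n_perm = cfg$n_perm)
  }

  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  persist <- report
  persist$elapsed_sec <- NULL   # keep the manifest byte-stable across reruns
  jsonlite::write_json(persist, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}

# evenly spaced disjoint planted activity programs over the plain gene range
make_default_planted <- function(n_genes, n_programs, frac, logfc,
                                 genes_per_program = 40) {
  if (n_programs == 0) return(list())
  lapply(seq_len(n_programs), function(p) {
    start <- floor(n_genes / 2) + (p - 1) * genes_per_program + 1
    list(genes = seq(start, length.out = genes_per_program),
         frac = frac, logfc = logfc)
  })
}
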