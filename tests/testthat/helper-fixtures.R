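# in-code fixtures shared across test files

# dense toy CountMatrix with optional metadata columns
make_cm <- function(counts, genes = NULL, cells = NULL, sample = NULL,
                    group = NULL, celltype = NULL) {
  counts <- as.matrix(counts)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(counts)))
  meta <- data.frame(cell_id = cells, stringsAsFactors = FALSE)
  if (!is.null(sample)) meta$sample <- sample
  if (!is.null(group)) meta$group <- group
  if (!is.null(celltype)) meta$celltype <- celltype
  CountMatrix(counts, gene_ids = genes, cell_ids = cells, cell_meta = meta)
}

rand_cm <- function(G, N, seed = 1, lambda = 2) {
  set.seed(seed)
  make_cm(matrix(rpois(G * N, lambda), G, N))
}

# hand-built GeneProgram for clustering / robustness tests
make_program <- function(sample_id, k, index, top_genes, weights = NULL) {
  if (is.null(weights)) weights <- rev(seq_along(top_genes))
  list(sample_id = sample_id, k = k, program_index = index,
       spectrum = stats::setNames(as.numeric(weights), top_genes),
       top_genes = top_genes)
}

# a family of programs sharing a planted gene pool, for MP recovery toys;
# index_offset keeps (sample, k, index) provenance unique across families
planted_program_family <- function(pool, n_programs, samples, k_values,
                                   shared = 40, total = 50, seed = 1,
                                   index_offset = 0) {
  set.seed(seed)
  lapply(seq_len(n_programs), function(i) {
    tg <- c(sample(pool, shared),
            sprintf("noise_%s_%02d_%02d", samples[(i - 1) %% length(samples) + 1],
                    i + index_offset, seq_len(total - shared)))
    make_program(samples[(i - 1) %% length(samples) + 1],
                 k_values[(i - 1) %% length(k_values) + 1], i + index_offset, tg)
  })
}
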