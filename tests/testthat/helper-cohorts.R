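# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, force(expr), .fixtures)
  get(key, .fixtures)
}

# small plain cohort with all default cell types
small_cohort <- function() memo("small", {
  generate_cohort(synthetic_config(n_samples = 4, cells_per_sample = 150,
                                   n_genes = 300, seed = 101))
})

# cohort with a planted ligand-receptor axis (effect 4)
axis_cohort <- function() memo("axis", {
  generate_cohort(synthetic_config(n_samples = 6, cells_per_sample = 200,
                                   n_genes = 400,
                                   lr_axis = lr_axis_spec(effect = 4),
                                   malignant_sample_fraction = 2 / 3,
                                   seed = 202))
})

# toy gene programs for robustness/clustering tests: a program with given
# genes, sample, K and factor index
toy_program <- function(genes, sample_id = "S1", K = 4L, factor_index = 1L) {
  structure(list(sample_id = sample_id, rank_K = as.integer(K),
                 factor_index = as.integer(factor_index),
                 top_genes = genes,
                 weights = rev(seq_along(genes)) / length(genes)),
            class = "gene_program")
}

gene_ids <- function(idx) sprintf("G%05d", idx)
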