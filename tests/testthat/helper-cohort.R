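# Shared fixtures, built in code and cached per test session.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a small cohort for fast module tests: 4 tissues x 24 samples, 120 species,
# one planted signature tissue
small_cohort <- function(seed = 11L) {
  cached(paste0("small", seed), generate_cohort(small_config(seed)))
}

small_config <- function(seed = 11L) {
  cohort_config(n_tissues = 4, samples_per_tissue = 24, n_species = 120,
                signature_tissues = 1, signature_species_per_tissue = 10,
                seed = seed)
}

# a reduced model spec for property tests where the result should not depend
# on the breadth of the hyperparameter grid
fast_spec <- function(iterations = 3L, master_seed = 1L, ...) {
  model_spec(interaction_depth_grid = 1:2, n_trees_grid = 50L,
             iterations = iterations, master_seed = master_seed, ...)
}

core_universe <- function(cohort, threshold = 0.10) {
  cores <- lapply(unique(cohort$metadata$tissue), function(t)
    core_microbiome(cohort$counts, cohort$metadata, t, threshold))
  core_union_and_intersections(cores)$union
}

# tiny deterministic count matrix with dimnames
toy_counts <- function(values, nrow, ncol) {
  matrix(as.integer(values), nrow, ncol,
         dimnames = list(sprintf("sp%02d", seq_len(nrow)),
                         sprintf("s%02d", seq_len(ncol))))
}
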