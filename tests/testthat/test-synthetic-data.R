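test_that("generation is deterministic and has the configured dimensions", {
  cfg <- cohort_config(n_tissues = 8, samples_per_tissue = 40, n_species = 300,
                       seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_equal(dim(a$counts), c(300L, 320L))
  expect_identical(colnames(a$counts), a$metadata$sample_id)
  expect_true(all(a$counts >= 0))
  expect_true(is.integer(a$counts))
  expect_equal(as.vector(table(a$metadata$tissue)), rep(40L, 8))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_tissues = 0), "n_tissues")
  expect_error(cohort_config(shared_core_fraction = 1.2), "shared_core_fraction")
  expect_error(cohort_config(signature_fold_change = -1), "signature_fold_change")
  expect_error(cohort_config(baseline_prevalence_range = c(0.6, 0.2)),
               "baseline_prevalence_range")
  expect_error(cohort_config(n_tissues = 4, signature_tissues = 1:2,
                             signature_species_per_tissue = 30, n_species = 50),
               "signature_species_per_tissue")
  expect_error(cohort_config(sites_per_tissue = 9, n_collection_sites = 6),
               "sites_per_tissue")
})

test_that("planted fold change shows up as the expected nonzero-mean ratio", {
  cfg <- cohort_config(samples_per_tissue = 200, signature_fold_change = 4,
                       seed = 4)
  co <- generate_cohort(cfg)
  sig <- co$signature_species[["tissue_01"]]
  expect_length(sig, 10)
  inside <- co$metadata$tissue == "tissue_01"
  v_in <- co$counts[sig, inside]
  v_out <- co$counts[sig, !inside]
  ratio <- mean(v_in[v_in > 0]) / mean(v_out[v_out > 0])
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("sparsity responds monotonically to baseline prevalence", {
  lo <- generate_cohort(cohort_config(n_tissues = 3, samples_per_tissue = 20,
                                      n_species = 150, signature_tissues = 1,
                                      baseline_prevalence_range = c(0.05, 0.25),
                                      seed = 5))
  hi <- generate_cohort(cohort_config(n_tissues = 3, samples_per_tissue = 20,
                                      n_species = 150, signature_tissues = 1,
                                      baseline_prevalence_range = c(0.4, 0.8),
                                      seed = 5))
  expect_gt(mean(lo$counts == 0), mean(hi$counts == 0))
})

test_that("without a planted effect no species separates tissues", {
  co <- generate_cohort(cohort_config(n_tissues = 4, samples_per_tissue = 30,
                                      n_species = 200, signature_tissues = 1,
                                      signature_fold_change = 1, seed = 6))
  inside <- co$metadata$tissue == "tissue_01"
  p <- apply(co$counts, 1, function(x) {
    if (sum(x) == 0) return(1)
    suppressWarnings(stats::wilcox.test(x[inside], x[!inside])$p.value)
  })
  expect_gte(mean(p >= 0.01, na.rm = TRUE), 0.95)
})

test_that("collection sites are tissue-linked and batches span the cohort", {
  co <- small_cohort()
  by_tissue <- table(co$metadata$tissue, co$metadata$collection_site)
  # each tissue is drawn from exactly sites_per_tissue sites
  expect_true(all(rowSums(by_tissue > 0) == 2))
  # batches are not tissue-linked
  by_batch <- table(co$metadata$tissue, co$metadata$isolation_batch)
  expect_true(all(rowSums(by_batch > 0) >= 3))
})

test_that("external cohorts share structure but not draws", {
  cfg <- small_config()
  ext <- generate_external_cohort(cfg, n_samples_per_tissue = 6)
  expect_equal(ncol(ext$counts), 24)
  expect_identical(rownames(ext$counts), sprintf("sp%04d", 1:120))
  expect_identical(ext$counts,
                   generate_external_cohort(cfg, n_samples_per_tissue = 6)$counts)
  # dropped features are all-zero rows
  expect_true(all(ext$counts[ext$dropped_features, ] == 0))
  expect_error(generate_external_cohort(cfg, n_samples_per_tissue = 0),
               "n_samples_per_tissue")
})

test_that("library-size shift halves the external depth", {
  cfg <- cohort_config(n_tissues = 3, samples_per_tissue = 40, n_species = 150,
                       signature_tissues = 1, seed = 8)
  co <- generate_cohort(cfg)
  ext <- generate_external_cohort(cfg, n_samples_per_tissue = 30,
                                  shift_library_size = 0.5)
  ratio <- mean(colSums(ext$counts)) / mean(colSums(co$counts))
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})

test_that("planted signatures are recovered downstream, non-planted are not", {
  # paired over seeds: the 1-vs-rest model must rank the planted tissue's
  # samples better than a non-planted tissue's in every cohort
  seeds <- 1:10
  diffs <- vapply(seeds, function(sd) {
    co <- generate_cohort(cohort_config(n_tissues = 4, samples_per_tissue = 24,
                                        n_species = 120, signature_tissues = 1,
                                        seed = sd))
    fu <- core_universe(co)
    spec <- fast_spec(iterations = 3L, master_seed = sd * 100L)
    planted <- run_signature_experiment(co$counts, co$metadata, "tissue_01",
                                        fu, spec)
    control <- run_signature_experiment(co$counts, co$metadata, "tissue_03",
                                        fu, spec)
    planted$mean_auroc - control$mean_auroc
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("a planted trait effect is recoverable from metadata", {
  co <- small_cohort()
  feat <- names(sort(rowMeans(co$counts > 0), decreasing = TRUE))[1]
  meta2 <- plant_trait_signal(co$metadata, co$counts, "age", feat,
                              type = "continuous")
  expect_gt(abs(cor(meta2$age, log1p(co$counts[feat, ]))), 0.99)
  meta3 <- plant_trait_signal(co$metadata, co$counts, "smoking", feat,
                              type = "binary")
  expect_setequal(unique(meta3$smoking), c("high", "low"))
})
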