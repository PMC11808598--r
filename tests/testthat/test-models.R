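test_that("stratified splits allocate per class and partition the cohort", {
  labels <- c(rep(TRUE, 10), rep(FALSE, 90))
  sp <- stratified_split(labels, 0.7, seed = 5)
  expect_equal(sum(labels[sp$train]), 7)
  expect_equal(sum(!labels[sp$train]), 63)
  expect_equal(sum(labels[sp$test]), 3)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(labels, 0.7, seed = 5))
  expect_false(identical(sp, stratified_split(labels, 0.7, seed = 6)))
  expect_error(stratified_split(c(TRUE, rep(FALSE, 5)), 0.7, 1), "at least 2")
})

test_that("up-sampling balances classes keeping every original sample", {
  labels <- c(rep(TRUE, 7), rep(FALSE, 63))
  idx <- seq_along(labels)
  up <- upsample_minority(idx, labels, seed = 3)
  expect_equal(sum(labels[up]), 63)
  expect_equal(sum(!labels[up]), 63)
  expect_true(all(idx %in% up))
  expect_identical(up, upsample_minority(idx, labels, seed = 3))
  balanced <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_identical(upsample_minority(1:10, balanced, 1), 1:10)
})

test_that("the booster separates Gaussian blobs perfectly", {
  set.seed(41)
  n <- 50
  X <- rbind(matrix(rnorm(n * 4, 0), n, 4), matrix(rnorm(n * 4, 3), n, 4))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c(0, 1), each = n)
  sp <- fast_spec()
  fit <- train_boosted_model(X, y, sp, seed = 1)
  hold <- rbind(matrix(rnorm(80, 0), 20, 4), matrix(rnorm(80, 3), 20, 4))
  colnames(hold) <- paste0("f", 1:4)
  rec <- evaluate(fit, hold, rep(c(0, 1), each = 20))
  expect_equal(rec$auroc, 1)
  expect_equal(sum(fit$importance_shares), 1, tolerance = 1e-9)
})

test_that("shuffled labels give chance-level cross-validated AUROC", {
  set.seed(43)
  X <- matrix(rnorm(60 * 10), 60, 10, dimnames = list(NULL, paste0("f", 1:10)))
  sp <- fast_spec()
  cv_auc <- replicate(20, {
    y <- sample(rep(c(0, 1), each = 30))
    fit <- train_boosted_model(X, y, sp, seed = sample.int(1e6, 1))
    mean(fit$cv_results$score, na.rm = TRUE)
  })
  expect_gt(mean(cv_auc), 0.3)
  expect_lt(mean(cv_auc), 0.7)
})

test_that("grid selection is deterministic and prefers the simpler model", {
  set.seed(47)
  X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.numeric(X[, 1] + rnorm(80, 0, 0.5) > 0)
  sp <- model_spec(iterations = 1)
  a <- train_boosted_model(X, y, sp, seed = 9)
  b <- train_boosted_model(X, y, sp, seed = 9)
  expect_equal(a$best_interaction_depth, b$best_interaction_depth)
  expect_equal(a$best_n_trees, b$best_n_trees)
  expect_equal(a$importance_shares, b$importance_shares)
  # grid rows are ordered depth-then-trees so ties resolve to the simplest
  expect_equal(a$cv_results$interaction_depth,
               rep(sp$interaction_depth_grid, each = 3))
  expect_error(train_boosted_model(X, rep(1, 80), sp, 1), "constant")
})

test_that("the signature experiment detects the planted tissue only", {
  co <- small_cohort()
  fu <- core_universe(co)
  spec <- fast_spec(iterations = 4L, master_seed = 7L)
  planted <- run_signature_experiment(co$counts, co$metadata, "tissue_01",
                                      fu, spec)
  control <- run_signature_experiment(co$counts, co$metadata, "tissue_04",
                                      fu, spec)
  expect_gt(planted$mean_auroc, control$mean_auroc)
  expect_gt(planted$mean_auroc, 0.7)
  expect_equal(nrow(planted$iterations), 4)
  expect_equal(planted$mean_auroc, mean(planted$iterations$auroc))
  expect_equal(planted$ci_margin$auroc, ci_margin(planted$iterations$auroc))
  expect_equal(sum(planted$importance_shares), 1, tolerance = 1e-9)
  # reruns reproduce: per-iteration seeds derive from the master seed
  again <- run_signature_experiment(co$counts, co$metadata, "tissue_01",
                                    fu, spec)
  expect_equal(planted$iterations, again$iterations)
})

test_that("signature verdicts apply both thresholds inclusively", {
  mk <- function(auroc, rel) list(mean_auroc = auroc, mean_relative_aupr = rel)
  expect_true(signature_verdict(mk(0.72, 1.5)))
  expect_false(signature_verdict(mk(0.69, 2.0)))
  expect_true(signature_verdict(mk(0.70, 1.4)))
  expect_false(signature_verdict(mk(0.90, 1.39)))
})

test_that("rank correlation matches hand-computed Spearman values", {
  expect_equal(rank_correlation(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(rank_correlation(1:3, c(3, 1, 2))$rho, -0.5)
  expect_equal(rank_correlation(1:4, 4:1)$rho, -1)
  expect_warning(rc <- rank_correlation(rep(1, 4), 1:4), "constant")
  expect_true(is.nan(rc$rho))
  expect_error(rank_correlation(1:2, 1:2), "at least 3")
})

test_that("small trait groups are skipped without training", {
  co <- small_cohort()
  res <- trait_experiment(co$counts, co$metadata, "tissue_01", "smoking",
                          spec = fast_spec(), min_group = 20)
  # 24 samples cannot contain two groups of 20
  expect_equal(res$status, "skipped")
  expect_match(res$reason, "insufficient")
})

test_that("a trait independent of the microbiome is unpredictable", {
  co <- cached("trait_null", generate_cohort(
    cohort_config(n_tissues = 1, samples_per_tissue = 200, n_species = 100,
                  signature_tissues = integer(0), seed = 21)))
  res <- trait_experiment(co$counts, co$metadata, "tissue_01", "drinking",
                          spec = fast_spec(iterations = 6L, master_seed = 3L),
                          min_group = 20)
  expect_equal(res$status, "ok")
  expect_equal(res$type, "categorical")
  expect_gt(res$mean_auroc, 0.4)
  expect_lt(res$mean_auroc, 0.6)
})

test_that("a planted continuous trait is recovered with high R-squared", {
  co <- cached("trait_planted", generate_cohort(
    cohort_config(n_tissues = 1, samples_per_tissue = 120, n_species = 80,
                  signature_tissues = integer(0), library_size_cv = 0.2,
                  seed = 22)))
  feat <- names(sort(rowMeans(co$counts), decreasing = TRUE))[1]
  meta2 <- plant_trait_signal(co$metadata, co$counts, "age", feat,
                              type = "continuous")
  res <- trait_experiment(co$counts, meta2, "tissue_01", "age",
                          spec = fast_spec(iterations = 3L, master_seed = 5L),
                          min_group = 20)
  expect_equal(res$status, "ok")
  expect_equal(res$type, "continuous")
  expect_gt(res$mean_r2, 0.9)
})
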