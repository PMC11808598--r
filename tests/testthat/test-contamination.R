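test_that("the default scenario has 12 contaminants, 6 per volume category", {
  co <- small_cohort()
  scen <- build_default_scenario(co$metadata, seed = 1)
  expect_length(scen$contaminants, 12)
  cats <- vapply(scen$contaminants, `[[`, character(1), "category")
  expect_equal(sum(cats == "high_volume"), 6)
  expect_equal(sum(cats == "low_volume"), 6)
  routes <- vapply(scen$contaminants, `[[`, character(1), "route")
  expect_equal(as.vector(table(routes)[c("collection_site", "isolation_batch",
                                         "sequencing_batch")]), rep(4L, 3))
  # high-volume: few samples within one unit; low-volume: broad across units
  for (cs in scen$contaminants) {
    if (cs$category == "high_volume") {
      expect_equal(cs$affected_fraction, 0.05)
      expect_equal(cs$linkage, "within_one_unit")
      expect_equal(cs$magnitude_quantile, 0.95)
    } else {
      expect_equal(cs$affected_fraction, 0.40)
      expect_equal(cs$linkage, "across_units")
      expect_equal(cs$magnitude_quantile, 0.25)
    }
  }
})

test_that("a metadata table missing a linkage route is rejected", {
  co <- small_cohort()
  meta2 <- co$metadata
  meta2$sequencing_batch <- NULL
  expect_error(build_default_scenario(meta2, 1), "sequencing_batch")
})

test_that("affected sets respect counts, linkage, and the iteration seed", {
  co <- small_cohort()
  scen <- build_default_scenario(co$metadata, seed = 1)
  a1 <- contamination_assignments(scen, iteration_seed = 100)
  a2 <- contamination_assignments(scen, iteration_seed = 100)
  expect_identical(a1, a2)
  n <- nrow(co$metadata)
  for (i in seq_along(scen$contaminants)) {
    cs <- scen$contaminants[[i]]
    hit <- a1[[cs$id]]
    if (cs$linkage == "within_one_unit") {
      units <- unique(co$metadata[[cs$route]][match(hit, co$metadata$sample_id)])
      expect_length(units, 1)
      expect_lte(length(hit), max(1, round(cs$affected_fraction * n)))
    } else {
      expect_equal(length(hit), round(cs$affected_fraction * n))
    }
  }
  # different iteration seeds redraw the affected sets
  draws <- lapply(1:10, function(s) contamination_assignments(scen, s))
  distinct <- vapply(2:10, function(k)
    !identical(draws[[k]], draws[[1]]), logical(1))
  expect_true(all(distinct))
})

test_that("a fully-sampled unit yields exactly the expected affected count", {
  meta <- data.frame(sample_id = sprintf("s%03d", 1:100),
                     tissue = "t1",
                     collection_site = "siteA",
                     isolation_batch = rep(c("i1", "i2"), 50),
                     sequencing_batch = rep(c("q1", "q2"), each = 50),
                     stringsAsFactors = FALSE)
  cs <- contaminant_spec("c1", "high_volume", "collection_site",
                         affected_fraction = 0.05, magnitude_quantile = 0.95,
                         linkage = "within_one_unit")
  scen <- contamination_scenario(list(cs), meta, 1)
  hit <- contamination_assignments(scen, 7)$c1
  expect_length(hit, 5)
  expect_true(all(hit %in% meta$sample_id))
})

test_that("injection appends contaminants without touching biology", {
  co <- small_cohort()
  nm <- css_normalize(co$counts)
  scen <- build_default_scenario(co$metadata, seed = 2)
  inj <- inject(nm, scen, iteration_seed = 9)
  expect_equal(nrow(inj$values), nrow(nm$values) + 12)
  expect_identical(inj$values[rownames(nm$values), ], nm$values)
  expect_identical(inj$scaling_factors, nm$scaling_factors)
  expect_identical(colnames(inj$values), colnames(nm$values))
  # affected cells carry the magnitude, the rest zero
  mags <- contaminant_magnitudes(nm, scen)
  aff <- attr(inj, "affected")
  for (id in scen$ids) {
    row <- inj$values[id, ]
    hit <- intersect(aff[[id]], colnames(nm$values))
    expect_true(all(row[hit] == mags[[id]]))
    expect_true(all(row[setdiff(names(row), hit)] == 0))
  }
  expect_error(inject(inj, scen, 9), "collide")
})

test_that("rank-sum comparisons match exact enumeration and handle identity", {
  # exact two-sided p for [1,2,3] vs [4,5,6] by enumerating C(6,3) splits
  pool <- 1:6
  splits <- combn(6, 3)
  stat <- apply(splits, 2, function(ix) sum(rank(pool)[ix]))
  observed <- sum(rank(pool)[1:3])
  p_exact <- mean(abs(stat - mean(stat)) >= abs(observed - mean(stat)))
  expect_equal(p_exact, 0.1)
  expect_equal(stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)

  it <- data.frame(auroc = rep(c(0.7, 0.72, 0.74), 4),
                   aupr = rep(c(0.4, 0.42, 0.44), 4))
  rep0 <- compare_and_verdict(it, it)
  expect_equal(rep0$p_auroc, 1)
  expect_equal(rep0$verdict, "resilient")
  expect_error(compare_and_verdict(it[1:5, ], it), "10 iterations")
})

test_that("verdict requires both significance and contaminant importance", {
  worse <- data.frame(auroc = seq(0.50, 0.59, length.out = 12),
                      aupr = seq(0.20, 0.29, length.out = 12))
  better <- data.frame(auroc = seq(0.80, 0.89, length.out = 12),
                       aupr = seq(0.50, 0.59, length.out = 12))
  contaminated <- list(tissue = "t", iterations = better,
                       contaminant_share = rep(0.30, 12),
                       mean_importance_shares =
                         c(sp1 = 0.4, sp2 = 0.3, c1 = 0.3),
                       contaminant_ids = "c1")
  v <- compare_and_verdict(contaminated, worse)
  expect_equal(v$verdict, "contamination_driven")
  expect_lt(v$p_auroc, 0.001)
  # same performance gap but no contaminant involvement stays resilient
  clean <- contaminated
  clean$contaminant_share <- rep(0.001, 12)
  clean$mean_importance_shares <- c(sp1 = 0.9, sp2 = 0.099, c1 = 0.001)
  v2 <- compare_and_verdict(clean, worse, top_k = 2)
  expect_equal(v2$verdict, "resilient")
})

test_that("zero-magnitude scenarios leave both arms identical", {
  co <- small_cohort()
  meta <- co$metadata
  null_specs <- lapply(1:12, function(i)
    contaminant_spec(sprintf("c%02d", i),
                     if (i <= 6) "high_volume" else "low_volume",
                     c("collection_site", "isolation_batch",
                       "sequencing_batch")[(i - 1) %% 3 + 1],
                     affected_fraction = 0.2, magnitude_quantile = 0,
                     linkage = "across_units"))
  scen <- contamination_scenario(null_specs, meta, 1)
  fu <- core_universe(co)
  res <- run_contamination_experiment(co$counts, meta, "tissue_01", fu, scen,
                                      fast_spec(iterations = 3L,
                                                master_seed = 2L))
  expect_equal(res$tissue_01$contaminated$iterations$auroc,
               res$tissue_01$uncontaminated$iterations$auroc,
               tolerance = 1e-9)
  expect_equal(res$tissue_01$contaminated$iterations$aupr,
               res$tissue_01$uncontaminated$iterations$aupr,
               tolerance = 1e-9)
})
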