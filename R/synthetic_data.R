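#' Configure a synthetic low-biomass microbial cohort
#'
#' Builds the parameter set for [generate_cohort()]. The generator emulates
#' the statistical structure of microbial taxonomic profiles recovered from
#' deep host RNA-seq: sparse, overdispersed counts at low classified depth
#' (tens of thousands of reads per sample), a core community shared across
#' tissues, planted tissue-specific signature species, and collection-site /
#' batch structure that can carry contaminant signal.
#'
#' Counts follow a zero-inflated negative binomial law: per species a
#' baseline detection prevalence, and, when present, a negative-binomial
#' magnitude whose mean combines a species-level abundance, a log-normal
#' per-sample library-size factor, and (for signature species in their
#' tissue) a multiplicative fold change.
#'
#' @param n_tissues number of tissues in the cohort.
#' @param samples_per_tissue samples drawn per tissue.
#' @param n_species size of the feature universe.
#' @param shared_core_fraction fraction of species forced to be prevalent
#'   (detection prevalence >= 0.5) in every tissue, emulating the shared
#'   cross-tissue core community.
#' @param signature_tissues integer indices of tissues that receive a planted
#'   microbial signature.
#' @param signature_species_per_tissue number of species whose abundance is
#'   shifted in each signature tissue.
#' @param signature_fold_change multiplicative shift applied to the
#'   negative-binomial mean of a signature species in its tissue's samples.
#' @param mean_library_size expected classified microbial reads per sample.
#' @param library_size_cv coefficient of variation of the log-normal
#'   per-sample library-size factor.
#' @param baseline_prevalence_range length-2 vector; baseline per-species
#'   detection prevalence is drawn uniformly from this interval.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param n_collection_sites,n_isolation_batches,n_sequencing_batches number
#'   of linkage units of each kind.
#' @param sites_per_tissue how many collection sites a tissue is sampled at;
#'   tissues are tied to specific sites so that site-linked contamination can
#'   confound tissue identity.
#' @param seed integer seed; the generator is deterministic given the config.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_tissues = 8,
                          samples_per_tissue = 40,
                          n_species = 300,
                          shared_core_fraction = 0.3,
                          signature_tissues = 1:3,
                          signature_species_per_tissue = 10,
                          signature_fold_change = 4,
                          mean_library_size = 4.2e4,
                          library_size_cv = 0.6,
                          baseline_prevalence_range = c(0.05, 0.6),
                          dispersion = 1,
                          n_collection_sites = 6,
                          n_isolation_batches = 4,
                          n_sequencing_batches = 4,
                          sites_per_tissue = 2,
                          seed = 1L) {
  cfg <- list(
    n_tissues = n_tissues,
    samples_per_tissue = samples_per_tissue,
    n_species = n_species,
    shared_core_fraction = shared_core_fraction,
    signature_tissues = as.integer(signature_tissues),
    signature_species_per_tissue = signature_species_per_tissue,
    signature_fold_change = signature_fold_change,
    mean_library_size = mean_library_size,
    library_size_cv = library_size_cv,
    baseline_prevalence_range = baseline_prevalence_range,
    dispersion = dispersion,
    n_collection_sites = n_collection_sites,
    n_isolation_batches = n_isolation_batches,
    n_sequencing_batches = n_sequencing_batches,
    sites_per_tissue = sites_per_tissue,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      stop_config(field, "must be a single integer >= 1")
  }
  for (f in c("n_tissues", "samples_per_tissue", "n_species",
              "signature_species_per_tissue", "n_collection_sites",
              "n_isolation_batches", "n_sequencing_batches",
              "sites_per_tissue"))
    chk_count(f)
  if (!is.numeric(cfg$shared_core_fraction) ||
      cfg$shared_core_fraction < 0 || cfg$shared_core_fraction > 1)
    stop_config("shared_core_fraction", "must be a proportion in [0,1]")
  if (length(cfg$signature_tissues) > 0 &&
      (any(cfg$signature_tissues < 1) ||
       any(cfg$signature_tissues > cfg$n_tissues) ||
       anyDuplicated(cfg$signature_tissues)))
    stop_config("signature_tissues", "must be distinct tissue indices in range")
  if (cfg$signature_species_per_tissue * length(cfg$signature_tissues) >
      cfg$n_species)
    stop_config("signature_species_per_tissue",
                "times the number of signature tissues exceeds n_species")
  if (!is.numeric(cfg$signature_fold_change) || cfg$signature_fold_change <= 0)
    stop_config("signature_fold_change", "must be a positive real")
  if (!is.numeric(cfg$mean_library_size) || cfg$mean_library_size <= 0)
    stop_config("mean_library_size", "must be positive")
  if (!is.numeric(cfg$library_size_cv) || cfg$library_size_cv <= 0)
    stop_config("library_size_cv", "must be positive")
  bp <- cfg$baseline_prevalence_range
  if (!is.numeric(bp) || length(bp) != 2L || any(bp < 0) || any(bp > 1) ||
      bp[1] > bp[2])
    stop_config("baseline_prevalence_range",
                "must be an increasing pair of proportions in [0,1]")
  if (!is.numeric(cfg$dispersion) || cfg$dispersion <= 0)
    stop_config("dispersion", "must be positive")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_config("seed", "must be a single integer")
  if (cfg$sites_per_tissue > cfg$n_collection_sites)
    stop_config("sites_per_tissue", "cannot exceed n_collection_sites")
  invisible(cfg)
}

# Species-level structural parameters shared between the training cohort and
# any external cohort generated from the same config: which species are core,
# which are signatures of which tissue. Draws nothing random.
cohort_structure <- function(cfg) {
  species <- sprintf("sp%04d", seq_len(cfg$n_species))
  n_core <- round(cfg$shared_core_fraction * cfg$n_species)
  core <- species[seq_len(n_core)]
  k <- length(cfg$signature_tissues)
  sig <- list()
  if (k > 0) {
    # signature blocks taken from the tail of the species list, disjoint
    # from each other (and from the shared core whenever sizes allow)
    start <- cfg$n_species - k * cfg$signature_species_per_tissue
    for (i in seq_len(k)) {
      idx <- start + (i - 1L) * cfg$signature_species_per_tissue +
        seq_len(cfg$signature_species_per_tissue)
      sig[[as.character(cfg$signature_tissues[i])]] <- species[idx]
    }
  }
  tissues <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))
  list(species = species, core = core, signature = sig, tissues = tissues)
}

# Draw species prevalences and per-species mean abundances. Signature
# species are modeled as core-like members of their community: prevalence
# drawn like shared-core species and abundance weights from the quantifiable
# (at-or-above-median) range of the community's log-normal abundance law. A
# tissue-specific signature only makes biological sense for taxa reliably
# observed and quantified in that tissue; a magnitude shift planted in a
# sporadic, barely-sequenced taxon would be unidentifiable at low-biomass
# depth and would not emulate the reported signature features, which are
# consistently detected core taxa.
draw_species_params <- function(cfg, st, mean_library_size,
                                dropped = character(0)) {
  n <- cfg$n_species
  prev <- stats::runif(n, cfg$baseline_prevalence_range[1],
                       cfg$baseline_prevalence_range[2])
  names(prev) <- st$species
  prev[st$core] <- stats::runif(length(st$core), 0.5, 0.9)
  sig_all <- unlist(st$signature, use.names = FALSE)
  if (length(sig_all))
    prev[sig_all] <- stats::runif(length(sig_all), 0.5, 0.9)
  # log-normal species abundance weights, rescaled so the expected classified
  # reads per sample (at unit library factor) equal mean_library_size
  w <- stats::rlnorm(n, meanlog = 0, sdlog = 1.5)
  names(w) <- st$species
  if (length(sig_all))  # half-normal on the log scale: upper half of the law
    w[sig_all] <- exp(abs(stats::rnorm(length(sig_all), 0, 1.5)))
  prev[dropped] <- 0
  mu <- w * mean_library_size / sum(prev * w)
  list(prevalence = prev, mu = mu)
}

sample_counts_zinb <- function(cfg, st, pars, meta, lib_factor) {
  n_samp <- nrow(meta)
  mu_mat <- matrix(pars$mu, nrow = cfg$n_species, ncol = n_samp,
                   dimnames = list(st$species, meta$sample_id))
  for (t_chr in names(st$signature)) {
    t_lab <- st$tissues[as.integer(t_chr)]
    cols <- meta$tissue == t_lab
    mu_mat[st$signature[[t_chr]], cols] <-
      mu_mat[st$signature[[t_chr]], cols] * cfg$signature_fold_change
  }
  mu_mat <- sweep(mu_mat, 2, lib_factor, "*")
  present <- matrix(
    stats::rbinom(cfg$n_species * n_samp, 1L, rep(pars$prevalence, n_samp)),
    nrow = cfg$n_species)
  counts <- matrix(
    stats::rnbinom(cfg$n_species * n_samp, size = cfg$dispersion,
                   mu = as.vector(mu_mat)),
    nrow = cfg$n_species, dimnames = dimnames(mu_mat))
  counts * present
}

round_robin_jitter <- function(units, n) {
  units[sample.int(length(units) * ceiling(n / length(units)))[seq_len(n)] %%
          length(units) + 1L]
}

draw_traits <- function(n) {
  data.frame(
    age = pmin(80, pmax(20, round(stats::rnorm(n, 55, 12)))),
    bmi = round(pmin(45, pmax(17, stats::rnorm(n, 27, 4))), 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    smoking = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.3, 0.7)),
    drinking = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.5, 0.5)),
    ancestry = sample(c("groupA", "groupB", "other"), n, replace = TRUE,
                      prob = c(0.55, 0.35, 0.10)),
    hypertension_history = stats::rbinom(n, 1, 0.25) == 1,
    diabetes2_history = stats::rbinom(n, 1, 0.12) == 1,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort of microbial taxonomic profiles
#'
#' Draws a complete taxon-by-sample count matrix plus sample metadata under
#' the zero-inflated negative-binomial model described in [cohort_config()].
#' Each tissue is sampled at `sites_per_tissue` specific collection sites
#' (sites cycle across tissues), while isolation and sequencing batches are
#' spread over all samples; this linkage structure is what the in-silico
#' contamination scenarios exploit. Traits are drawn independently of the
#' microbial counts, so trait models are null by construction; use
#' [plant_trait_signal()] to add a real trait effect for power testing.
#'
#' @param config a [cohort_config()].
#' @return list with `counts` (integer matrix, species x samples) and
#'   `metadata` (data.frame: sample_id, subject_id, tissue, collection_site,
#'   isolation_batch, sequencing_batch, traits), plus the `signature_species`
#'   map and the `config` used.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_tissues = 3,
#'   samples_per_tissue = 10, n_species = 60, signature_tissues = 1))
#' dim(cohort$counts)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  st <- cohort_structure(config)
  n_samp <- config$n_tissues * config$samples_per_tissue
  with_seed(config$seed, {
    meta <- data.frame(
      sample_id = sprintf("smp%04d", seq_len(n_samp)),
      subject_id = sprintf("sub%04d", seq_len(n_samp)),
      tissue = rep(st$tissues, each = config$samples_per_tissue),
      stringsAsFactors = FALSE)
    # tissues are collected at specific sites (consecutive blocks of the
    # site list, wrapping around), samples alternating among them
    site_ids <- sprintf("site_%02d", seq_len(config$n_collection_sites))
    meta$collection_site <- unlist(lapply(seq_len(config$n_tissues), function(t) {
      own <- site_ids[((t - 1L) * config$sites_per_tissue +
                         seq_len(config$sites_per_tissue) - 1L) %%
                        config$n_collection_sites + 1L]
      round_robin_jitter(own, config$samples_per_tissue)
    }))
    meta$isolation_batch <- round_robin_jitter(
      sprintf("iso_%02d", seq_len(config$n_isolation_batches)), n_samp)
    meta$sequencing_batch <- round_robin_jitter(
      sprintf("seq_%02d", seq_len(config$n_sequencing_batches)), n_samp)
    meta <- cbind(meta, draw_traits(n_samp))

    pars <- draw_species_params(config, st, config$mean_library_size)
    sdlog <- sqrt(log(1 + config$library_size_cv^2))
    lib <- stats::rlnorm(n_samp, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    counts <- sample_counts_zinb(config, st, pars, meta, lib)
    storage.mode(counts) <- "integer"
    sig_named <- st$signature
    if (length(sig_named))
      names(sig_named) <- st$tissues[as.integer(names(sig_named))]
    list(counts = counts, metadata = meta,
         signature_species = sig_named, config = config)
  })
}

#' Generate an independent external cohort sharing a training cohort's
#' signature structure
#'
#' Emulates testing trained tissue models on a second, independently
#' collected dataset: the same feature universe and the same planted
#' signature species with the same effect direction, but independently drawn
#' species baselines, its own library-size scale, and a fraction of training
#' features entirely absent (all-zero rows) to exercise feature alignment.
#'
#' @param config the [cohort_config()] of the training cohort.
#' @param n_samples_per_tissue samples per tissue in the external cohort.
#' @param shift_library_size multiplier on the expected library size,
#'   emulating cross-study depth shift.
#' @param tissues integer indices of tissues to include (default all).
#' @param drop_feature_fraction fraction of non-core, non-signature species
#'   absent from the external dataset.
#' @param keep_signatures set `FALSE` to generate an external cohort with the
#'   planted effects removed (a transfer null).
#' @return list as in [generate_cohort()].
#' @export
generate_external_cohort <- function(config, n_samples_per_tissue = 6,
                                     shift_library_size = 1,
                                     tissues = seq_len(config$n_tissues),
                                     drop_feature_fraction = 0.1,
                                     keep_signatures = TRUE) {
  validate_cohort_config(config)
  if (!is.numeric(n_samples_per_tissue) || n_samples_per_tissue < 1)
    stop("n_samples_per_tissue must be >= 1", call. = FALSE)
  if (!is.numeric(shift_library_size) || shift_library_size <= 0)
    stop("shift_library_size must be positive", call. = FALSE)
  st <- cohort_structure(config)
  cfg <- config
  if (!keep_signatures) cfg$signature_fold_change <- 1
  tissues <- as.integer(tissues)
  n_samp <- length(tissues) * n_samples_per_tissue
  with_seed(config$seed + 77003L, {
    meta <- data.frame(
      sample_id = sprintf("ext%04d", seq_len(n_samp)),
      subject_id = sprintf("esub%04d", seq_len(n_samp)),
      tissue = rep(st$tissues[tissues], each = n_samples_per_tissue),
      collection_site = "ext_site",
      isolation_batch = "ext_iso",
      sequencing_batch = "ext_seq",
      stringsAsFactors = FALSE)
    meta <- cbind(meta, draw_traits(n_samp))
    droppable <- setdiff(st$species,
                         c(st$core, unlist(st$signature, use.names = FALSE)))
    dropped <- sample(droppable,
                      round(drop_feature_fraction * length(droppable)))
    pars <- draw_species_params(cfg, st,
                                cfg$mean_library_size * shift_library_size,
                                dropped = dropped)
    sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
    lib <- stats::rlnorm(n_samp, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    counts <- sample_counts_zinb(cfg, st, pars, meta, lib)
    storage.mode(counts) <- "integer"
    sig_named <- st$signature
    if (length(sig_named))
      names(sig_named) <- st$tissues[as.integer(names(sig_named))]
    list(counts = counts, metadata = meta, signature_species = sig_named,
         dropped_features = dropped, config = config)
  })
}

#' Plant a trait effect into cohort metadata
#'
#' Overwrites one metadata trait with a deterministic (optionally noisy)
#' function of a single microbial feature, for power-testing the trait
#' models. Continuous traits become a linear function of the log count;
#' binary traits split at the feature's median.
#'
#' @param metadata,counts a cohort's metadata and counts.
#' @param trait metadata column to overwrite.
#' @param feature feature (row of `counts`) driving the trait.
#' @param type `"continuous"` or `"binary"`.
#' @param noise_sd Gaussian noise added to a continuous trait.
#' @return the modified metadata.
#' @export
plant_trait_signal <- function(metadata, counts, trait, feature,
                               type = c("continuous", "binary"),
                               noise_sd = 0) {
  type <- match.arg(type)
  if (!feature %in% rownames(counts))
    stop("feature not found in counts", call. = FALSE)
  x <- log1p(counts[feature, metadata$sample_id])
  if (type == "continuous") {
    metadata[[trait]] <- 50 + 10 * as.numeric(scale(x)) +
      stats::rnorm(length(x), 0, noise_sd)
  } else {
    metadata[[trait]] <- ifelse(x > stats::median(x), "high", "low")
  }
  metadata
}
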