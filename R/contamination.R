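# In-silico contamination resilience testing.
#
# Pseudo-contaminant features are appended to CSS-normalized profiles to ask
# whether a tissue classifier's performance could be explained by
# contamination entering at the collection site, the nucleic-acid isolation
# step, or the sequencing step, rather than by tissue biology. Two volume
# categories are simulated: high-volume contaminants hitting few samples
# (would be spotted if widespread) and low-volume contaminants touching many
# samples at small magnitude (evade detection). A signature is called
# contamination-resilient when contaminated and uncontaminated model
# performance are statistically indistinguishable and the model does not
# lean on contaminant features.

#' Specify a single pseudo-contaminant
#'
#' @param id contaminant feature ID (must not collide with biological
#'   features).
#' @param category `"high_volume"` or `"low_volume"`.
#' @param route linkage route: `"collection_site"`, `"isolation_batch"` or
#'   `"sequencing_batch"`.
#' @param affected_fraction fraction of the cohort's samples contaminated
#'   per iteration.
#' @param magnitude_quantile quantile of the pooled nonzero normalized
#'   abundances at which the contaminant's value is set.
#' @param linkage `"within_one_unit"` (affected samples drawn inside one
#'   unit of the route, redrawn per iteration unless `unit` is fixed) or
#'   `"across_units"` (drawn from the whole cohort).
#' @param unit optional fixed unit label for `within_one_unit` linkage,
#'   e.g. to model a contaminant systematically tied to one collection site.
#' @return a `contaminant_spec` list.
#' @export
contaminant_spec <- function(id, category = c("high_volume", "low_volume"),
                             route = c("collection_site", "isolation_batch",
                                       "sequencing_batch"),
                             affected_fraction,
                             magnitude_quantile,
                             linkage = c("within_one_unit", "across_units"),
                             unit = NA_character_) {
  category <- match.arg(category)
  route <- match.arg(route)
  linkage <- match.arg(linkage)
  if (affected_fraction <= 0 || affected_fraction > 1)
    stop_config("affected_fraction", "must lie in (0,1]")
  if (magnitude_quantile < 0 || magnitude_quantile > 1)
    stop_config("magnitude_quantile", "must lie in [0,1]")
  structure(list(id = id, category = category, route = route,
                 affected_fraction = affected_fraction,
                 magnitude_quantile = magnitude_quantile,
                 linkage = linkage, unit = unit),
            class = "contaminant_spec")
}

#' Build the default 12-contaminant scenario
#'
#' Per route (collection site, isolation batch, sequencing batch): two
#' high-volume contaminants (5% of samples, drawn within one randomly
#' chosen unit per iteration, magnitude at the 0.95 quantile of nonzero
#' normalized abundances) and two low-volume contaminants (40% of samples
#' drawn across units, magnitude at the 0.25 quantile) — 12 contaminants,
#' six per volume category. The magnitudes and fractions are configurable
#' model choices: the volume categories are defined qualitatively
#' (few-samples/high-abundance vs many-samples/low-abundance) and these
#' defaults realize them.
#'
#' @param metadata sample metadata; must carry all three linkage columns.
#' @param seed scenario seed (stored; per-iteration draws derive from the
#'   iteration seed).
#' @return a `contamination_scenario`: contaminant specs plus the cohort's
#'   sample-to-unit table.
#' @export
build_default_scenario <- function(metadata, seed = 1L) {
  routes <- c("collection_site", "isolation_batch", "sequencing_batch")
  missing <- setdiff(routes, names(metadata))
  if (length(missing))
    stop("metadata lacks linkage column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  specs <- list()
  n <- 0L
  for (r in routes) {
    for (k in 1:2) {
      n <- n + 1L
      specs[[n]] <- contaminant_spec(sprintf("contam_%02d", n), "high_volume",
                                     r, affected_fraction = 0.05,
                                     magnitude_quantile = 0.95,
                                     linkage = "within_one_unit")
    }
    for (k in 1:2) {
      n <- n + 1L
      specs[[n]] <- contaminant_spec(sprintf("contam_%02d", n), "low_volume",
                                     r, affected_fraction = 0.40,
                                     magnitude_quantile = 0.25,
                                     linkage = "across_units")
    }
  }
  contamination_scenario(specs, metadata, seed)
}

#' Assemble a contamination scenario from contaminant specs
#'
#' @param contaminants list of [contaminant_spec()] objects.
#' @param metadata cohort metadata with the linkage columns used by the
#'   specs.
#' @param seed stored scenario seed.
#' @return a `contamination_scenario`.
#' @export
contamination_scenario <- function(contaminants, metadata, seed = 1L) {
  ids <- vapply(contaminants, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate contaminant IDs", call. = FALSE)
  routes <- unique(vapply(contaminants, `[[`, character(1), "route"))
  missing <- setdiff(routes, names(metadata))
  if (length(missing))
    stop("metadata lacks linkage column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  units <- metadata[, c("sample_id", intersect(
    c("collection_site", "isolation_batch", "sequencing_batch"),
    names(metadata))), drop = FALSE]
  structure(list(contaminants = contaminants, ids = ids,
                 sample_units = units, seed = as.integer(seed)),
            class = "contamination_scenario")
}

#' Draw the per-iteration contaminated sample sets
#'
#' The affected set of every contaminant is redrawn each iteration: the
#' affected count is `round(affected_fraction * n_cohort_samples)` (at
#' least 1), drawn within one unit of the contaminant's route for
#' `within_one_unit` linkage (capped at the unit's size) or across the
#' whole cohort otherwise.
#'
#' @param scenario a `contamination_scenario`.
#' @param iteration_seed seed for this iteration's draw.
#' @return named list of affected sample-ID vectors, one per contaminant.
#' @export
contamination_assignments <- function(scenario, iteration_seed) {
  su <- scenario$sample_units
  n_total <- nrow(su)
  with_seed(iteration_seed, {
    out <- lapply(scenario$contaminants, function(cs) {
      n_aff <- max(1L, round(cs$affected_fraction * n_total))
      if (cs$linkage == "within_one_unit") {
        units <- unique(su[[cs$route]])
        unit <- if (!is.na(cs$unit)) cs$unit else sample(units, 1L)
        pool <- su$sample_id[su[[cs$route]] == unit]
        if (length(pool) == 0L)
          stop("contaminant unit '", unit, "' has no samples", call. = FALSE)
        sample(pool, min(n_aff, length(pool)))
      } else {
        sample(su$sample_id, n_aff)
      }
    })
    names(out) <- scenario$ids
    out
  })
}

#' Inject pseudo-contaminants into a normalized matrix
#'
#' Appends one feature row per contaminant: affected samples receive the
#' contaminant's magnitude (the `magnitude_quantile` of the matrix's pooled
#' nonzero normalized values — constant across its affected samples),
#' all other samples 0. Biological rows, sample order and normalization
#' metadata are untouched. Injection happens after CSS normalization, so
#' contaminants do not perturb the scaling factors.
#'
#' @param nm a `css_matrix`.
#' @param scenario a `contamination_scenario`.
#' @param iteration_seed seed used to draw affected sets (ignored when
#'   `assignments` is supplied).
#' @param assignments optional precomputed [contamination_assignments()],
#'   so that the train and test splits of one iteration share a single
#'   cohort-wide draw.
#' @param magnitudes optional named numeric vector of per-contaminant
#'   magnitudes (from [contaminant_magnitudes()]), so both splits of an
#'   iteration carry the same contaminant amount; by default magnitudes are
#'   derived from `nm` itself.
#' @return a `css_matrix` with the contaminant rows appended and the
#'   affected sets attached as attribute `"affected"`.
#' @export
inject <- function(nm, scenario, iteration_seed = 1L, assignments = NULL,
                   magnitudes = NULL) {
  if (!inherits(nm, "css_matrix"))
    stop("inject() operates on a CSS-normalized matrix", call. = FALSE)
  if (any(scenario$ids %in% rownames(nm$values)))
    stop("contaminant IDs collide with existing features", call. = FALSE)
  if (is.null(assignments))
    assignments <- contamination_assignments(scenario, iteration_seed)
  if (is.null(magnitudes)) magnitudes <- contaminant_magnitudes(nm, scenario)
  rows <- matrix(0, nrow = length(scenario$contaminants), ncol = ncol(nm$values),
                 dimnames = list(scenario$ids, colnames(nm$values)))
  for (i in seq_along(scenario$contaminants)) {
    cs <- scenario$contaminants[[i]]
    hit <- intersect(assignments[[cs$id]], colnames(nm$values))
    rows[i, hit] <- magnitudes[[cs$id]]
  }
  out <- nm
  out$values <- rbind(nm$values, rows)
  attr(out, "affected") <- assignments
  out
}

#' Contaminant magnitudes from a normalized matrix
#'
#' Each contaminant's magnitude is the `magnitude_quantile` of the matrix's
#' pooled nonzero normalized values (0 meaning a null contaminant). In the
#' paired experiment the magnitudes of an iteration are derived from its
#' training split and reused for the test split, mirroring how a physical
#' contaminant contributes the same read volume wherever it appears.
#'
#' @param nm a `css_matrix`.
#' @param scenario a `contamination_scenario`.
#' @return named numeric vector, one magnitude per contaminant.
#' @export
contaminant_magnitudes <- function(nm, scenario) {
  pooled <- nm$values[nm$values > 0]
  if (length(pooled) == 0L)
    stop("normalized matrix has no nonzero values", call. = FALSE)
  vapply(scenario$contaminants, function(cs) {
    if (cs$magnitude_quantile == 0) 0 else
      stats::quantile(pooled, probs = cs$magnitude_quantile,
                      names = FALSE, type = 7)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(scenario$ids)
}

#' Run paired contaminated / uncontaminated model streams
#'
#' For each tissue: `spec$iterations` paired iterations. Both arms share
#' the iteration's split seed; the contaminated arm injects the scenario's
#' contaminants (one cohort-wide draw per iteration) into the train and
#' test normalized matrices and adds the contaminant IDs to the feature
#' universe.
#'
#' @param counts raw count matrix.
#' @param metadata aligned metadata.
#' @param tissues tissue labels to test.
#' @param feature_universe biological model features.
#' @param scenario a `contamination_scenario`.
#' @param spec a [model_spec()].
#' @param quantile,scale_constant CSS parameters.
#' @return named list per tissue: `contaminated` and `uncontaminated`
#'   results, each with an `iterations` table; the contaminated arm also
#'   carries per-iteration total contaminant importance shares and the mean
#'   importance ranking.
#' @export
run_contamination_experiment <- function(counts, metadata, tissues,
                                         feature_universe, scenario,
                                         spec = model_spec(),
                                         quantile = 0.5,
                                         scale_constant = 1000) {
  validate_metadata(metadata, counts)
  if (length(tissues) < 1L) stop("no tissues given", call. = FALSE)
  universe_c <- c(feature_universe, scenario$ids)
  out <- lapply(tissues, function(tissue) {
    labels <- metadata$tissue == tissue
    iters_u <- vector("list", spec$iterations)
    iters_c <- vector("list", spec$iterations)
    for (i in seq_len(spec$iterations)) {
      seed <- spec$master_seed + i
      assign_i <- contamination_assignments(scenario, seed)
      iters_u[[i]] <- run_iteration(counts, labels, feature_universe, spec,
                                    seed = seed, quantile = quantile,
                                    scale_constant = scale_constant)
      # magnitudes are fixed from the first (training) split of the
      # iteration so both splits carry the same contaminant amount
      mags_i <- NULL
      iters_c[[i]] <- run_iteration(
        counts, labels, universe_c, spec, seed = seed,
        quantile = quantile, scale_constant = scale_constant,
        mutate_nm = function(nm, s) {
          if (is.null(mags_i)) mags_i <<- contaminant_magnitudes(nm, scenario)
          inject(nm, scenario, s, assignments = assign_i,
                 magnitudes = mags_i)
        })
    }
    contam_share <- vapply(iters_c, function(x)
      sum(x$model$importance_shares[scenario$ids]), numeric(1))
    imp_mat <- vapply(iters_c, function(x) x$model$importance_shares,
                      numeric(length(universe_c)))
    mean_imp <- rowMeans(imp_mat)
    list(tissue = tissue,
         uncontaminated = list(tissue = tissue,
                               iterations = summarize_iterations(iters_u)),
         contaminated = list(tissue = tissue,
                             iterations = summarize_iterations(iters_c),
                             contaminant_share = contam_share,
                             mean_importance_shares = mean_imp,
                             contaminant_ids = scenario$ids))
  })
  names(out) <- tissues
  out
}

#' Compare arms and issue a resilience verdict
#'
#' Two-sided unpaired Wilcoxon rank-sum tests on AUROC and on AUPR between
#' contaminated and uncontaminated iterations. A tissue's signature is
#' called `contamination_driven` when performance is significantly higher
#' with contaminants (both metrics, p < `alpha`, contaminated medians
#' higher) AND contaminants play an important role in the model (total mean
#' importance share >= `share_threshold`, or any contaminant among the
#' `top_k` mean importances); otherwise `resilient`.
#'
#' @param contaminated,uncontaminated per-arm results for one tissue (as
#'   returned in [run_contamination_experiment()] elements), or plain
#'   data.frames with `auroc` and `aupr` columns.
#' @param alpha significance level.
#' @param share_threshold total contaminant importance share considered
#'   "important".
#' @param top_k importance rank considered "important".
#' @return a `resilience_report`.
#' @export
compare_and_verdict <- function(contaminated, uncontaminated, alpha = 0.05,
                                share_threshold = 0.05, top_k = 10) {
  it_c <- if (is.data.frame(contaminated)) contaminated else contaminated$iterations
  it_u <- if (is.data.frame(uncontaminated)) uncontaminated else uncontaminated$iterations
  if (nrow(it_c) < 10L || nrow(it_u) < 10L)
    stop("need at least 10 iterations per arm", call. = FALSE)
  p_auroc <- suppressWarnings(
    stats::wilcox.test(it_c$auroc, it_u$auroc, exact = NULL)$p.value)
  p_aupr <- suppressWarnings(
    stats::wilcox.test(it_c$aupr, it_u$aupr, exact = NULL)$p.value)
  med_up <- stats::median(it_c$auroc) > stats::median(it_u$auroc) &&
    stats::median(it_c$aupr) > stats::median(it_u$aupr)

  share_total <- 0
  top_rank <- NA_integer_
  if (!is.data.frame(contaminated) &&
      !is.null(contaminated$contaminant_share)) {
    share_total <- mean(contaminated$contaminant_share)
    ranks <- rank(-contaminated$mean_importance_shares, ties.method = "min")
    top_rank <- min(ranks[contaminated$contaminant_ids])
  }
  important <- share_total >= share_threshold ||
    (!is.na(top_rank) && top_rank <= top_k)
  driven <- (p_auroc < alpha && p_aupr < alpha && med_up) && important
  structure(list(tissue = if (!is.data.frame(contaminated))
                   contaminated$tissue else NA_character_,
                 p_auroc = p_auroc, p_aupr = p_aupr,
                 medians_higher_contaminated = med_up,
                 contaminant_importance_share_total = share_total,
                 top_rank_of_any_contaminant = top_rank,
                 verdict = if (driven) "contamination_driven" else "resilient"),
            class = "resilience_report")
}

#' @export
print.resilience_report <- function(x, ...) {
  cat(sprintf("Contamination resilience: %s\n", x$verdict))
  cat(sprintf("  Wilcoxon p (AUROC) = %.3g, p (AUPR) = %.3g; contaminant share %.3f; best rank %s\n",
              x$p_auroc, x$p_aupr, x$contaminant_importance_share_total,
              x$top_rank_of_any_contaminant))
  invisible(x)
}
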