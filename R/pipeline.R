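# End-to-end orchestration: simulate or load profiles, build per-tissue
# cores and their union, run the iterated 1-vs-rest models, apply the
# signature criterion, contamination-test the verdict-positive tissues,
# and (optionally) transfer-test resilient tissues on an external cohort.

#' Run the full signature-detection pipeline
#'
#' Stages, in order: load or simulate the cohort; optional genus
#' aggregation; per-tissue core microbiomes at the prevalence threshold;
#' core union (the model feature universe); per-tissue iterated 1-vs-rest
#' signature experiments; signature verdicts; in-silico contamination
#' experiment on the verdict-positive tissues with resilience verdicts;
#' optional external transfer with a shuffled-label null on the resilient
#' tissues. Every stage logs its parameters and seeds to `message()`, and
#' intermediate artifacts are written under `output_dir` when given.
#'
#' @param config named list (or path to a YAML file readable by
#'   `yaml::read_yaml`) with any of:
#'   \describe{
#'     \item{counts, metadata}{paths to TSVs, or in-memory objects; when
#'       absent a synthetic cohort is generated from `cohort`.}
#'     \item{cohort}{list of [cohort_config()] arguments for simulation.}
#'     \item{taxonomy}{optional taxonomy TSV path or named vector; when
#'       present counts are aggregated to genus before analysis.}
#'     \item{spec}{list of [model_spec()] arguments.}
#'     \item{prevalence_threshold}{core threshold, default 0.10.}
#'     \item{auroc_min, rel_aupr_min}{signature thresholds, 0.70 / 1.4.}
#'     \item{alpha}{significance level, 0.05.}
#'     \item{contamination}{logical, default TRUE.}
#'     \item{transfer}{logical, default FALSE; external cohort is generated
#'       with [generate_external_cohort()] unless `external_counts` /
#'       `external_metadata` paths are supplied.}
#'     \item{tissues}{subset of tissues to model (default all).}
#'     \item{output_dir}{directory for artifacts (optional).}
#'     \item{seed}{master seed, default 1.}
#'   }
#' @return a run report list; also serialized as `report.json` under
#'   `output_dir` when set. Identical config and seed reproduce the report
#'   byte for byte.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_artifact <- function(obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    } else if (is.data.frame(obj)) {
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      write_count_table(obj, path)
    }
    invisible(path)
  }

  stage <- function(name, ...) message(sprintf("[%s] %s", name, sprintf(...)))

  # --- load or simulate ------------------------------------------------
  if (!is.null(config$counts)) {
    counts <- if (is.character(config$counts)) read_count_table(config$counts)
              else config$counts
    meta <- if (is.character(config$metadata))
              read_sample_metadata(config$metadata) else config$metadata
    cohort <- NULL
    stage("input", "loaded %d features x %d samples", nrow(counts), ncol(counts))
  } else {
    ccfg <- do.call(cohort_config, c(config$cohort %||% list(),
                                     if (is.null(config$cohort$seed))
                                       list(seed = seed)))
    cohort <- generate_cohort(ccfg)
    counts <- cohort$counts
    meta <- cohort$metadata
    stage("simulate", "generated %d species x %d samples (seed %d)",
          nrow(counts), ncol(counts), ccfg$seed)
    save_artifact(counts, "counts.tsv")
    save_artifact(meta, "metadata.tsv")
  }
  validate_count_matrix(counts)
  validate_metadata(meta, counts)

  if (!is.null(config$taxonomy)) {
    tax <- if (is.character(config$taxonomy) &&
               length(config$taxonomy) == 1L && is.null(names(config$taxonomy)))
      read_taxonomy(config$taxonomy) else config$taxonomy
    counts <- aggregate_taxa(counts, tax)
    stage("aggregate", "aggregated to %d taxa", nrow(counts))
  }

  thr <- config$prevalence_threshold %||% 0.10
  auroc_min <- config$auroc_min %||% 0.70
  rel_aupr_min <- config$rel_aupr_min %||% 1.4
  alpha <- config$alpha %||% 0.05
  tissues <- config$tissues %||% unique(meta$tissue)
  spec <- do.call(model_spec, c(config$spec %||% list(),
                                if (is.null(config$spec$master_seed))
                                  list(master_seed = seed)))

  # --- cores -----------------------------------------------------------
  cores <- lapply(tissues, function(t) core_microbiome(counts, meta, t, thr))
  cu <- core_union_and_intersections(cores)
  stage("core", "union of per-tissue cores: %d species (threshold %.0f%%)",
        length(cu$union), 100 * thr)
  save_artifact(data.frame(species = cu$union), "core_union.tsv")
  save_artifact(cu$intersections, "core_intersections.tsv")

  # --- signature experiments -------------------------------------------
  signatures <- lapply(tissues, function(t) {
    stage("classify", "tissue %s: %d iterations", t, spec$iterations)
    run_signature_experiment(counts, meta, t, cu$union, spec)
  })
  names(signatures) <- tissues
  verdicts <- vapply(signatures, signature_verdict, logical(1),
                     auroc_min = auroc_min, rel_aupr_min = rel_aupr_min)
  sig_tab <- data.frame(
    tissue = tissues,
    mean_auroc = vapply(signatures, `[[`, numeric(1), "mean_auroc"),
    mean_relative_aupr = vapply(signatures, `[[`, numeric(1),
                                "mean_relative_aupr"),
    signature = unname(verdicts))
  save_artifact(sig_tab, "signature_verdicts.tsv")
  stage("verdict", "%d/%d tissues signature-positive",
        sum(verdicts), length(verdicts))

  report <- list(
    parameters = list(seed = seed, prevalence_threshold = thr,
                      auroc_min = auroc_min, rel_aupr_min = rel_aupr_min,
                      alpha = alpha, spec = unclass(spec)),
    core_union_size = length(cu$union),
    signatures = lapply(signatures, function(s)
      list(tissue = s$tissue, mean_auroc = s$mean_auroc,
           mean_aupr = s$mean_aupr,
           mean_relative_aupr = s$mean_relative_aupr,
           ci_margin = s$ci_margin,
           iterations = s$iterations)),
    signature_verdicts = as.list(verdicts))

  # --- contamination ---------------------------------------------------
  resilient <- tissues[verdicts]
  if (isTRUE(config$contamination %||% TRUE) && sum(verdicts) > 0) {
    scenario <- build_default_scenario(meta, seed)
    stage("contaminate", "testing %d verdict-positive tissues, %d contaminants",
          sum(verdicts), length(scenario$contaminants))
    cres <- run_contamination_experiment(counts, meta, tissues[verdicts],
                                         cu$union, scenario, spec)
    reports <- lapply(cres, function(x)
      compare_and_verdict(x$contaminated, x$uncontaminated, alpha))
    res_tab <- data.frame(
      tissue = names(cres),
      p_auroc = vapply(reports, `[[`, numeric(1), "p_auroc"),
      p_aupr = vapply(reports, `[[`, numeric(1), "p_aupr"),
      contaminant_share = vapply(reports, `[[`, numeric(1),
                                 "contaminant_importance_share_total"),
      verdict = vapply(reports, `[[`, character(1), "verdict"))
    save_artifact(res_tab, "resilience_verdicts.tsv")
    report$resilience <- lapply(reports, unclass)
    resilient <- names(cres)[vapply(reports, function(r)
      r$verdict == "resilient", logical(1))]
    stage("contaminate", "%d/%d tissues resilient",
          length(resilient), sum(verdicts))
  }

  # --- transfer --------------------------------------------------------
  if (isTRUE(config$transfer) && length(resilient) > 0) {
    if (!is.null(config$external_counts)) {
      ext_counts <- if (is.character(config$external_counts))
        read_count_table(config$external_counts) else config$external_counts
      ext_meta <- if (is.character(config$external_metadata))
        read_sample_metadata(config$external_metadata) else config$external_metadata
    } else {
      if (is.null(cohort))
        stop("transfer stage needs external_counts or a simulated cohort",
             call. = FALSE)
      ext <- generate_external_cohort(cohort$config,
                                      n_samples_per_tissue =
                                        config$external_samples_per_tissue %||% 6)
      ext_counts <- ext$counts
      ext_meta <- ext$metadata
    }
    stage("validate", "transfer-testing %d resilient tissues on %d external samples",
          length(resilient), ncol(ext_counts))
    transfers <- lapply(resilient, function(t) {
      trained <- run_signature_experiment(counts, meta, t, cu$union, spec,
                                          store_models = TRUE)
      nullres <- random_label_null(counts, meta, t, cu$union, spec)
      rep_t <- transfer_report(t, transfer_test(trained, ext_counts, ext_meta),
                               transfer_test(nullres, ext_counts, ext_meta))
      rep_t$preserved <- transfer_verdict(rep_t, alpha, auroc_min, rel_aupr_min)
      rep_t
    })
    names(transfers) <- resilient
    report$transfer <- lapply(transfers, unclass)
    stage("validate", "%d/%d tissues preserved externally",
          sum(vapply(transfers, `[[`, logical(1), "preserved")),
          length(transfers))
  }

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
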