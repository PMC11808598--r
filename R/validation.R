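# Cross-dataset transfer validation against a shuffled-label null.
#
# Trained tissue models are scored on an independently normalized external
# cohort; the chance distribution comes from models retrained after uniform
# permutation of the tissue labels (retraining, not score permutation, so
# the null inherits every pipeline artifact the true models are subject to).

#' Score stored signature models on an external cohort
#'
#' The external counts are CSS-normalized independently of the training
#' data (no scaling factor crosses datasets), aligned onto the training
#' feature universe (missing features zero-filled, extra features dropped),
#' and every stored iteration model is evaluated.
#'
#' @param result a `signature_result` trained with `store_models = TRUE`
#'   (from [run_signature_experiment()] or [random_label_null()]).
#' @param external_counts raw count matrix of the external cohort.
#' @param external_meta external metadata (tissue labels; must contain
#'   positives and negatives for the result's tissue).
#' @return data.frame of per-iteration metrics on the external set.
#' @export
transfer_test <- function(result, external_counts, external_meta) {
  if (is.null(result$models))
    stop("result carries no stored models; rerun with store_models = TRUE",
         call. = FALSE)
  validate_metadata(external_meta, external_counts)
  labels <- external_meta$tissue == result$tissue
  if (!any(labels) || all(labels))
    stop("external cohort lacks positives or negatives for tissue ",
         result$tissue, call. = FALSE)
  nm <- css_normalize(external_counts, result$quantile, result$scale_constant)
  X <- t(align_features(nm$values, result$feature_universe)$matrix)
  recs <- lapply(result$models, function(m) metrics_record(predict(m, X), labels))
  data.frame(
    iteration = seq_along(recs),
    auroc = vapply(recs, `[[`, numeric(1), "auroc"),
    aupr = vapply(recs, `[[`, numeric(1), "aupr"),
    aupr_random = vapply(recs, `[[`, numeric(1), "aupr_random"),
    relative_aupr = vapply(recs, `[[`, numeric(1), "relative_aupr"))
}

#' Shuffled-label null models
#'
#' Repeats the signature experiment with tissue labels permuted uniformly
#' at random before each iteration's split, normalization and training.
#' Class counts are preserved by construction. Models are stored for
#' external scoring.
#'
#' @inheritParams run_signature_experiment
#' @return a `signature_result` whose iterations come from label-shuffled
#'   models.
#' @export
random_label_null <- function(counts, metadata, target_tissue,
                              feature_universe, spec = model_spec(),
                              quantile = 0.5, scale_constant = 1000) {
  validate_metadata(metadata, counts)
  labels <- metadata$tissue == target_tissue
  iters <- lapply(seq_len(spec$iterations), function(i) {
    seed <- spec$master_seed + i
    shuffled <- with_seed(seed + 500009L, sample(labels))
    run_iteration(counts, shuffled, feature_universe, spec, seed = seed,
                  quantile = quantile, scale_constant = scale_constant)
  })
  tab <- summarize_iterations(iters)
  structure(list(tissue = target_tissue, iterations = tab,
                 mean_auroc = mean(tab$auroc),
                 mean_aupr = mean(tab$aupr),
                 mean_relative_aupr = mean(tab$relative_aupr),
                 feature_universe = feature_universe,
                 quantile = quantile, scale_constant = scale_constant,
                 spec = spec, null = TRUE,
                 models = lapply(iters, `[[`, "model")),
            class = "signature_result")
}

#' Assemble a transfer report for one tissue
#'
#' @param tissue tissue label.
#' @param true_metrics,null_metrics per-iteration metric tables from
#'   [transfer_test()] applied to the true-label and shuffled-label models.
#' @return a `transfer_report` with Wilcoxon p-values (two-sided, unpaired)
#'   for AUROC and AUPR and the external means.
#' @export
transfer_report <- function(tissue, true_metrics, null_metrics) {
  p_auroc <- suppressWarnings(
    stats::wilcox.test(true_metrics$auroc, null_metrics$auroc)$p.value)
  p_aupr <- suppressWarnings(
    stats::wilcox.test(true_metrics$aupr, null_metrics$aupr)$p.value)
  structure(list(tissue = tissue,
                 true_metrics = true_metrics, null_metrics = null_metrics,
                 mean_auroc = mean(true_metrics$auroc),
                 mean_relative_aupr = mean(true_metrics$relative_aupr),
                 p_auroc = p_auroc, p_aupr = p_aupr,
                 medians_higher_true =
                   stats::median(true_metrics$auroc) >
                     stats::median(null_metrics$auroc) &&
                   stats::median(true_metrics$aupr) >
                     stats::median(null_metrics$aupr)),
            class = "transfer_report")
}

#' Transfer verdict: is the signature preserved in the external cohort?
#'
#' Preserved requires (i) true models significantly outperform the
#' shuffled-label null on the external set (both metrics, p < `alpha`,
#' true medians higher) and (ii) absolute external performance clears the
#' signature thresholds (mean AUROC >= `auroc_min`, mean relative AUPR >=
#' `rel_aupr_min`). A model can be significantly better than chance yet
#' fail the absolute bar.
#'
#' @param report a [transfer_report()].
#' @param alpha significance level.
#' @param auroc_min,rel_aupr_min absolute thresholds.
#' @return logical.
#' @export
transfer_verdict <- function(report, alpha = 0.05, auroc_min = 0.70,
                             rel_aupr_min = 1.4) {
  sig <- report$p_auroc < alpha && report$p_aupr < alpha &&
    isTRUE(report$medians_higher_true)
  sig && report$mean_auroc >= auroc_min &&
    report$mean_relative_aupr >= rel_aupr_min
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("Transfer report for %s: external mean AUROC %.3f, relative AUPR %.2f\n",
              x$tissue, x$mean_auroc, x$mean_relative_aupr))
  cat(sprintf("  vs shuffled-label null: p (AUROC) = %.3g, p (AUPR) = %.3g\n",
              x$p_auroc, x$p_aupr))
  invisible(x)
}
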