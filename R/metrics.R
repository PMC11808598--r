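# Ranking metrics for the 1-vs-rest tissue classifiers. AUROC uses the
# rank-statistic (Mann-Whitney) form with ties averaged; AUPR uses
# step integration of the precision-recall curve over distinct score
# thresholds. The random-classifier PR baseline is the positive-class
# prevalence, so relative AUPR = 1 means chance and 1/prevalence is the
# ceiling attained by a perfect ranking.

#' Area under the ROC curve
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical (or 0/1) true class labels.
#' @return AUROC in `[0,1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC requires both classes in the evaluated set", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step integration over distinct score thresholds, descending: AUPR =
#' sum over thresholds of (recall increment) x precision. Tied scores are
#' handled as a single threshold.
#'
#' @inheritParams auroc
#' @return AUPR in `[0,1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0L || all(labels))
    stop("AUPR requires both classes in the evaluated set", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # block boundaries at distinct score values
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  n_at <- last
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Performance record for one evaluated model
#'
#' @inheritParams auroc
#' @return list: `auroc`, `aupr`, `aupr_random` (positive prevalence of the
#'   evaluated set), `relative_aupr` = `aupr / aupr_random`.
#' @export
metrics_record <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("evaluated set must contain both classes", call. = FALSE)
  p <- mean(labels)
  a <- aupr(scores, labels)
  list(auroc = auroc(scores, labels), aupr = a, aupr_random = p,
       relative_aupr = a / p)
}

#' Normal-approximation 95% confidence-interval margin over iterations
#'
#' @param x per-iteration metric values.
#' @return `1.96 * sd(x) / sqrt(length(x))`.
#' @export
ci_margin <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
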