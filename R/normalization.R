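# Cumulative sum scaling (CSS) for sparse low-biomass count profiles.
#
# CSS divides each sample by the cumulative count of its lower-abundance
# taxa, up to a chosen quantile, instead of by the full library size. The
# low tail of the abundance distribution is relatively stable across samples
# while a handful of dominant taxa can swamp total-sum scaling, so CSS is
# robust exactly where sparse microbial profiles are fragile. Scaling is
# always fit separately per dataset or data split: factors estimated on a
# training split are never applied to test samples.

#' Per-sample CSS scaling factors
#'
#' For sample j, the factor is the sum of its nonzero counts that are less
#' than or equal to the `quantile`-th quantile of the sample's nonzero
#' counts (linear-interpolation quantile; ties included). Zeros are excluded
#' throughout: in profiles this sparse, zeros carry no depth information.
#'
#' @param m count matrix, features x samples.
#' @param quantile quantile in (0,1); 0.5 targets the lower half of the
#'   nonzero abundance distribution.
#' @return named numeric vector of positive per-sample factors. An all-zero
#'   sample gets factor 1 with a warning (it carries no information).
#' @export
css_scaling_factors <- function(m, quantile = 0.5) {
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1)
    stop("quantile must lie in (0,1)", call. = FALSE)
  s <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    nz <- x[x > 0]
    if (length(nz) == 0L) {
      warning(sprintf("sample '%s' is all-zero; scaling factor set to 1",
                      colnames(m)[j]), call. = FALSE)
      return(1)
    }
    q <- stats::quantile(nz, probs = quantile, names = FALSE, type = 7)
    sum(nz[nz <= q])
  }, numeric(1))
  names(s) <- colnames(m)
  s
}

#' CSS-normalize a count matrix
#'
#' Each count is scaled by `scale_constant / s_j` with `s_j` the sample's
#' CSS factor, so zero counts stay zero and within-sample ratios among
#' retained taxa are preserved. The constant only rescales all features
#' uniformly (tree-based classifiers are invariant to it); 1000 is a common
#' convention.
#'
#' @inheritParams css_scaling_factors
#' @param scale_constant positive constant the factors are rescaled to.
#' @param log if `TRUE`, apply log2(x + 1) after scaling. Off by default;
#'   the classification engine consumes the linear scale.
#' @return a `css_matrix`: list with `values` (numeric matrix), per-sample
#'   `scaling_factors`, `quantile`, `scale_constant`, `log`.
#' @examples
#' m <- matrix(c(10L, 20L, 30L, 40L), 4, 1,
#'             dimnames = list(paste0("sp", 1:4), "s1"))
#' css_scaling_factors(m, 0.5)  # quantile 25 -> 10 + 20 = 30
#' @export
css_normalize <- function(m, quantile = 0.5, scale_constant = 1000,
                          log = FALSE) {
  validate_count_matrix(m)
  if (!is.numeric(scale_constant) || scale_constant <= 0)
    stop("scale_constant must be positive", call. = FALSE)
  s <- css_scaling_factors(m, quantile)
  values <- sweep(m, 2, s, "/") * scale_constant
  if (log) values <- log2(values + 1)
  structure(list(values = values, scaling_factors = s, quantile = quantile,
                 scale_constant = scale_constant, log = log),
            class = "css_matrix")
}

#' @export
print.css_matrix <- function(x, ...) {
  cat(sprintf("CSS-normalized matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  quantile %.2f, scale constant %g, log transform %s\n",
              x$quantile, x$scale_constant, if (x$log) "on" else "off"))
  invisible(x)
}

#' Data-adaptive choice of the CSS quantile
#'
#' Scans candidate quantiles l = 0.01 ... 0.99 and, at each l, measures the
#' median across samples of the absolute deviation between each sample's
#' l-th nonzero-count quantile and the l-th quantile of the across-sample
#' median count profile. The chosen l is the smallest at which this
#' deviation grows by more than 10% relative to the previous candidate
#' (instability onset), floored at 0.5. This is an approximation of the
#' adaptive procedure of reference CSS implementations, which pick the
#' quantile where sample quantiles start diverging; it is exposed behind a
#' flag and the fixed default 0.5 is used otherwise.
#'
#' @param m count matrix with at least two samples.
#' @return selected quantile in `[0.5, 0.99]`.
#' @export
select_quantile_adaptive <- function(m) {
  if (ncol(m) < 2L) stop("need at least two samples", call. = FALSE)
  ls <- seq(0.01, 0.99, by = 0.01)
  med_profile <- apply(m, 1, stats::median)
  ref_nz <- med_profile[med_profile > 0]
  if (length(ref_nz) == 0L) return(0.5)
  dev <- vapply(ls, function(l) {
    ref <- stats::quantile(ref_nz, probs = l, names = FALSE, type = 7)
    qj <- vapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      nz <- x[x > 0]
      if (length(nz) == 0L) return(NA_real_)
      stats::quantile(nz, probs = l, names = FALSE, type = 7)
    }, numeric(1))
    stats::median(abs(qj - ref), na.rm = TRUE)
  }, numeric(1))
  unstable <- which(dev[-1] > dev[-length(dev)] * 1.1 &
                      dev[-length(dev)] > 0) + 1L
  if (length(unstable) == 0L) return(0.5)
  max(0.5, ls[unstable[1]])
}
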