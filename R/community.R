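# Alpha diversity and core-microbiome construction.

#' Microbial richness of a sample
#'
#' Number of taxa with non-zero abundance. For a matrix, one value per
#' sample (column).
#'
#' @param x numeric vector of counts, or a features x samples matrix.
#' @return integer count, or named integer vector for a matrix.
#' @export
richness <- function(x) {
  if (is.matrix(x)) return(colSums(x > 0))
  sum(x > 0)
}

#' Shannon diversity index of a sample
#'
#' H = -sum p_i log p_i over nonzero proportions, natural log (computed via
#' \code{vegan::diversity}). For a matrix, one value per sample.
#'
#' @param x numeric vector of counts, or a features x samples matrix.
#' @return Shannon index (NaN with a warning for an all-zero sample, where
#'   the index is undefined).
#' @export
shannon <- function(x) {
  if (is.matrix(x)) {
    h <- vegan::diversity(t(x), index = "shannon")
    zero <- colSums(x) == 0
    if (any(zero)) {
      warning("Shannon index undefined for all-zero sample(s)", call. = FALSE)
      h[zero] <- NaN
    }
    return(h)
  }
  if (sum(x) == 0) {
    warning("Shannon index undefined for an all-zero sample", call. = FALSE)
    return(NaN)
  }
  unname(vegan::diversity(x, index = "shannon"))
}

#' Core microbiome of a tissue
#'
#' Retains every species present (raw count > 0) in at least `threshold` of
#' the tissue's samples, boundary inclusive. The 10% default keeps taxa
#' consistently observed in a tissue while discarding sporadic detections
#' that may reflect opportunistic infection or noise.
#'
#' @param m count matrix.
#' @param metadata sample metadata with `sample_id` and `tissue`.
#' @param tissue tissue label.
#' @param threshold prevalence threshold in `[0,1]`.
#' @return a `core_set`: list with `tissue`, `species`, `prevalence` (for
#'   members), `threshold`, `n_samples`.
#' @export
core_microbiome <- function(m, metadata, tissue, threshold = 0.10) {
  validate_metadata(metadata)
  if (!tissue %in% metadata$tissue)
    stop("unknown tissue: ", tissue, call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0,1]", call. = FALSE)
  ids <- metadata$sample_id[metadata$tissue == tissue]
  sub <- m[, ids, drop = FALSE]
  prev <- rowMeans(sub > 0)
  keep <- prev >= threshold & prev > 0
  structure(list(tissue = tissue, species = rownames(m)[keep],
                 prevalence = prev[keep], threshold = threshold,
                 n_samples = length(ids)),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("Core microbiome of %s: %d species (prevalence >= %.0f%% of %d samples)\n",
              x$tissue, length(x$species), 100 * x$threshold, x$n_samples))
  invisible(x)
}

#' Union and exclusive intersections of per-tissue core sets
#'
#' The union across tissues is the classifier feature universe. The
#' intersection table uses UpSet semantics: each species is counted in
#' exactly one class, defined by its full membership pattern across the
#' core sets.
#'
#' @param cores list of `core_set` objects (or plain character vectors,
#'   named by tissue).
#' @return list: `union` (character vector) and `intersections` (data.frame
#'   with `pattern` — tissue names joined by `&` — `degree`, and `size`,
#'   sorted by decreasing size).
#' @export
core_union_and_intersections <- function(cores) {
  if (length(cores) == 0L) stop("need at least one core set", call. = FALSE)
  sets <- lapply(cores, function(cs)
    if (inherits(cs, "core_set")) cs$species else as.character(cs))
  labs <- vapply(seq_along(cores), function(i) {
    cs <- cores[[i]]
    if (inherits(cs, "core_set")) cs$tissue
    else names(cores)[i] %||% as.character(i)
  }, character(1))
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, labs))
  pattern <- apply(membership, 1, function(row)
    paste(labs[row], collapse = "&"))
  tab <- table(pattern)
  inter <- data.frame(pattern = names(tab),
                      degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                      size = as.integer(tab), stringsAsFactors = FALSE)
  inter <- inter[order(-inter$size, inter$pattern), , drop = FALSE]
  rownames(inter) <- NULL
  list(union = universe, intersections = inter)
}
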