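#' Read a taxon-by-sample count table from TSV
#'
#' Expects a tab-separated table whose first column holds unique feature
#' identifiers (species or genus names) and whose header names the samples.
#' Cells must be non-negative integers; malformed input is rejected with the
#' offending line number.
#'
#' @param path TSV file path.
#' @return integer matrix, features x samples.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty count table: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (length(samples) < 1L)
    stop("count table header has no sample columns", call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in header", call. = FALSE)
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  feats <- character(length(body))
  m <- matrix(0L, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    f <- fields[[i]]
    if (length(f) != length(samples) + 1L)
      stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                   i + 1L, length(samples) + 1L, length(f)), call. = FALSE)
    feats[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v))
      stop(sprintf("non-numeric cell at line %d", i + 1L), call. = FALSE)
    if (any(v < 0))
      stop(sprintf("negative count at line %d", i + 1L), call. = FALSE)
    if (any(v != round(v)))
      stop(sprintf("non-integer count at line %d", i + 1L), call. = FALSE)
    m[i, ] <- as.integer(v)
  }
  if (anyDuplicated(feats))
    stop("duplicate feature identifiers in first column", call. = FALSE)
  dimnames(m) <- list(feats, samples)
  m
}

#' Write a count (or normalized) matrix as TSV
#'
#' First column `feature_id`, remaining columns one per sample. Inverse of
#' [read_count_table()] for integer matrices.
#'
#' @param m matrix with feature rownames and sample colnames.
#' @param path output path.
#' @export
write_count_table <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata as TSV
#'
#' Metadata must contain at least `sample_id` and `tissue`; linkage columns
#' (`collection_site`, `isolation_batch`, `sequencing_batch`) and traits are
#' carried through untouched.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(meta)
  meta
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column species-to-genus taxonomy map
#'
#' @param path TSV with columns `species`, `genus` (no header required to be
#'   named exactly; first column is the finer rank).
#' @return named character vector, species -> genus.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy map needs two columns", call. = FALSE)
  tax <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  if (anyDuplicated(names(tax)))
    stop("taxonomy maps a species to more than one genus", call. = FALSE)
  if (any(!nzchar(tax)))
    stop("taxonomy contains empty genus identifiers", call. = FALSE)
  tax
}

#' Aggregate a species-level count matrix to a coarser taxonomic rank
#'
#' Genus counts are the per-sample sums of member species counts, computed on
#' raw counts (aggregate before normalizing). Per-sample totals are conserved.
#'
#' @param m count matrix (species x samples).
#' @param taxonomy named character vector, species -> genus.
#' @return count matrix, genera x samples.
#' @export
aggregate_taxa <- function(m, taxonomy) {
  missing <- setdiff(rownames(m), names(taxonomy))
  if (length(missing))
    stop("species missing from taxonomy map: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10),
         call. = FALSE)
  agg <- rowsum(m, group = taxonomy[rownames(m)])
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Align a matrix onto a reference feature universe
#'
#' Reorders rows to exactly `reference_features`; features absent from `m`
#' are zero-filled (absence of evidence encoded as zero abundance, matching
#' how the classifiers are trained on sparse profiles), features outside the
#' reference are dropped.
#'
#' @param m numeric matrix with feature rownames (counts or normalized).
#' @param reference_features ordered character vector of feature IDs.
#' @return list: `matrix` (|reference| x samples), `n_filled`, `n_dropped`,
#'   `filled`, `dropped`.
#' @export
align_features <- function(m, reference_features) {
  if (length(reference_features) == 0L)
    stop("reference feature list is empty", call. = FALSE)
  if (anyDuplicated(reference_features))
    stop("reference feature list has duplicates", call. = FALSE)
  filled <- setdiff(reference_features, rownames(m))
  dropped <- setdiff(rownames(m), reference_features)
  out <- matrix(0, nrow = length(reference_features), ncol = ncol(m),
                dimnames = list(reference_features, colnames(m)))
  keep <- intersect(reference_features, rownames(m))
  out[keep, ] <- m[keep, ]
  list(matrix = out, n_filled = length(filled), n_dropped = length(dropped),
       filled = filled, dropped = dropped)
}
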