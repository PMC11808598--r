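# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never clobbers user-level reproducibility.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# A count matrix is a plain integer matrix, features x samples, with unique
# non-empty dimnames. Kept as base matrix so subsetting stays idiomatic.
validate_count_matrix <- function(m, arg = "counts") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("'%s' must be a numeric matrix (features x samples)", arg),
         call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(sprintf("'%s' must have feature rownames and sample colnames", arg),
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop(sprintf("'%s' has duplicate feature identifiers", arg), call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop(sprintf("'%s' has duplicate sample identifiers", arg), call. = FALSE)
  if (anyNA(m) || any(m < 0))
    stop(sprintf("'%s' contains missing or negative values", arg), call. = FALSE)
  if (any(m != round(m)))
    stop(sprintf("'%s' contains non-integer values", arg), call. = FALSE)
  invisible(m)
}

validate_metadata <- function(meta, m = NULL) {
  if (!is.data.frame(meta) || !"sample_id" %in% names(meta) ||
      !"tissue" %in% names(meta))
    stop("metadata must be a data.frame with 'sample_id' and 'tissue' columns",
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("metadata has duplicate sample identifiers", call. = FALSE)
  if (!is.null(m) && !identical(colnames(m), meta$sample_id))
    stop("metadata rows must match count matrix columns (same samples, same order)",
         call. = FALSE)
  invisible(meta)
}
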