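# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

stop_format <- function(fmt, ...) {
  stop(sprintf(paste0("format error: ", fmt), ...), call. = FALSE)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with integer stream indices (e.g. chromosome index,
#' motif slot) into a new seed below 2^31, so that independent stages of a
#' simulation draw from deterministic, non-colliding substreams.
#'
#' @param seed master integer seed.
#' @param ... integer stream indices.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(abs(seed)) %% 2147483629
  for (k in idx) {
    x <- (x * 48271 + (as.double(k) + 1) * 7919) %% 2147483629
  }
  as.integer(x) + 1L
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Signed inner gap between two 0-based half-open intervals on one chromosome:
# positive = bases strictly between them, negative = overlap depth,
# 0 = abutting. Symmetric in its arguments.
interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(b_start - a_end, a_start - b_end)
}

# Empty motif-hit table (the common currency of the scanning stage).
empty_hits <- function() {
  data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    strand = character(0), motif = character(0), seq = character(0),
    stringsAsFactors = FALSE
  )
}

is_hits_df <- function(x) {
  is.data.frame(x) &&
    all(c("chrom", "start", "end", "strand", "motif") %in% names(x))
}

is_pairs_df <- function(x) {
  is.data.frame(x) &&
    all(c("chrom", "re_start", "re_end", "are_start", "are_end",
          "spacer", "span_start", "span_end") %in% names(x))
}

is_peaks_df <- function(x) {
  is.data.frame(x) &&
    all(c("chrom", "start", "end", "center") %in% names(x))
}
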