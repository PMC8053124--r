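# Randomized-genome null model: the same numbers of RE and ARE motifs as
# observed in the real genome, placed uniformly at random on hypothetical
# chromosomes, allocated to chromosomes in proportion to their length.
# The null is positional only -- no nucleotide sequence is realized, since
# only distances are consumed downstream.

#' Specify a randomized-genome null
#'
#' @param chrom_lengths named vector of chromosome lengths (bases).
#' @param n_re,n_are total motif counts to place (match the observed
#'   genome-wide totals to mirror the real analysis).
#' @param re_length,are_length motif lengths in bases.
#' @param seed master integer seed; placement uses deterministic
#'   per-chromosome substreams derived from it.
#' @param allow_overlap permit random motifs to overlap one another
#'   (default TRUE, the pure uniform null); FALSE uses rejection sampling
#'   with a retry cap.
#' @return an object of class `null_genome_spec`.
#' @export
null_genome_spec <- function(chrom_lengths, n_re, n_are,
                             re_length = 20, are_length = 9,
                             seed = 1L, allow_overlap = TRUE) {
  if (length(chrom_lengths) == 0 || is.null(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths)))) {
    stop_usage("chrom_lengths must be a non-empty named vector")
  }
  if (any(chrom_lengths <= 0)) stop_usage("chromosome lengths must be positive")
  if (n_re < 0 || n_are < 0) stop_usage("motif counts must be non-negative")
  if (re_length < 1 || are_length < 1) stop_usage("motif lengths must be >= 1")
  structure(
    list(chrom_lengths = chrom_lengths, n_re = n_re, n_are = n_are,
         re_length = re_length, are_length = are_length,
         seed = as.integer(seed), allow_overlap = allow_overlap),
    class = "null_genome_spec"
  )
}

#' @export
print.null_genome_spec <- function(x, ...) {
  cat(sprintf(
    "Null genome spec: %d chromosome(s), %.0f bp; %.0f RE (%d bp), %.0f ARE (%d bp); seed %d\n",
    length(x$chrom_lengths), sum(x$chrom_lengths), x$n_re, x$re_length,
    x$n_are, x$are_length, x$seed))
  invisible(x)
}

#' Allocate motif counts to chromosomes proportionally to length
#'
#' Largest-remainder rounding of `total * L_i / sum(L)`: every chromosome
#' gets the floor of its exact share, and the leftover units go to the
#' chromosomes with the largest fractional remainders (ties broken by input
#' order). Counts always sum exactly to `total`.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param total total count to distribute (non-negative integer).
#' @return named integer-valued vector summing to `total`.
#' @export
allocate_counts <- function(chrom_lengths, total) {
  if (length(chrom_lengths) == 0) stop_usage("need at least one chromosome")
  if (sum(chrom_lengths) <= 0) stop_usage("zero-length genome")
  if (total < 0) stop_usage("total must be non-negative")
  quota <- total * chrom_lengths / sum(chrom_lengths)
  base <- floor(quota)
  left <- round(total - sum(base))
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(base, names(chrom_lengths))
}

place_on_chromosome <- function(len, count, motif_length, seed,
                                allow_overlap) {
  n_slots <- len - motif_length + 1
  if (count == 0) return(numeric(0))
  if (n_slots < 1 || (!allow_overlap && count * motif_length > len)) {
    stop("simulation error: cannot place ", count, " motifs of length ",
         motif_length, " on a chromosome of length ", len, call. = FALSE)
  }
  with_seed(seed, {
    if (allow_overlap) {
      sort(sample.int(n_slots, count, replace = TRUE) - 1)
    } else {
      # gap transform: strictly increasing draws on a shrunken range map
      # bijectively (and uniformly) onto sorted starts with pairwise
      # distance >= motif_length
      k <- n_slots - (count - 1) * (motif_length - 1)
      if (k < count) {
        stop("simulation error: cannot place ", count,
             " non-overlapping motifs of length ", motif_length,
             " on a chromosome of length ", len, call. = FALSE)
      }
      z <- sort(sample.int(k, count, replace = FALSE))
      z - 1 + (seq_len(count) - 1) * (motif_length - 1)
    }
  })
}

#' Place random motif instances under a null spec
#'
#' Uniform random starts in `[0, L - motif_length]` on each chromosome, with
#' chromosome counts from [allocate_counts()]. Placement is positional: the
#' hits carry no realized sequence and are assigned to the '+' strand.
#'
#' @param spec a [null_genome_spec()].
#' @param motif `"RE"` or `"ARE"`.
#' @return motif-hit data.frame (seq is `NA`), reproducible for a given
#'   spec seed.
#' @export
place_random_motifs <- function(spec, motif = c("RE", "ARE")) {
  motif <- match.arg(motif)
  mlen <- if (motif == "RE") spec$re_length else spec$are_length
  moff <- if (motif == "RE") 1L else 2L
  counts <- allocate_counts(spec$chrom_lengths, if (motif == "RE")
    spec$n_re else spec$n_are)
  out <- lapply(seq_along(counts), function(i) {
    starts <- place_on_chromosome(
      spec$chrom_lengths[[i]], counts[[i]], mlen,
      seed = derive_seed(spec$seed, i, moff),
      allow_overlap = spec$allow_overlap
    )
    data.frame(chrom = rep(names(counts)[i], length(starts)),
               start = starts, end = starts + mlen,
               strand = rep("+", length(starts)),
               motif = rep(motif, length(starts)),
               seq = rep(NA_character_, length(starts)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate null RE-ARE pairs and their spacer distribution
#'
#' Places RE and ARE hits independently under the spec and runs the same
#' nearest-neighbour pairing as the real analysis.
#'
#' @param spec a [null_genome_spec()].
#' @param max_window,steric_threshold,one_to_one passed to [pair_nearest()].
#' @return list with `pairs` (pair table) and `spacers` (numeric vector).
#' @export
simulate_null_pairs <- function(spec, max_window = Inf, steric_threshold = 7,
                                one_to_one = FALSE) {
  re <- place_random_motifs(spec, "RE")
  are <- place_random_motifs(spec, "ARE")
  pairs <- pair_nearest(re, are, max_window = max_window,
                        steric_threshold = steric_threshold,
                        one_to_one = one_to_one)
  list(pairs = pairs, spacers = pairs$spacer)
}
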