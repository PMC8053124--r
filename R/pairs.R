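# Nearest-neighbour RE-to-ARE pairing, spacer statistics, the steric
# feasibility rule, and pair-sequence export.
#
# The "spacer" is the inner gap between the two motif matches: the number
# of bases strictly between them (negative when the matches overlap, 0 when
# they abut). Simultaneous p63/NRF2 binding requires a spacer strictly
# greater than the steric threshold (default 7 bp).

orientation_of <- function(spacer, re_start, are_start) {
  ifelse(spacer < 0, "overlapping",
         ifelse(re_start <= are_start, "RE_upstream", "ARE_upstream"))
}

#' Spacer between one RE hit and one ARE hit
#'
#' The signed inner gap between two motif intervals on the same chromosome:
#' `max(b_start - a_end, a_start - b_end)`. Positive values count the bases
#' strictly between the motifs, 0 means they abut, negative values measure
#' overlap depth. Symmetric in its arguments.
#'
#' @param re_hit,are_hit one-row motif-hit data.frames (chrom, start, end).
#' @return integer spacer, with the relative orientation
#'   (`RE_upstream`, `ARE_upstream`, `overlapping`) as attribute
#'   `"orientation"`.
#' @export
spacer <- function(re_hit, are_hit) {
  if (re_hit$chrom[1] != are_hit$chrom[1]) {
    stop_usage("spacer() requires hits on the same chromosome")
  }
  s <- interval_gap(re_hit$start[1], re_hit$end[1],
                    are_hit$start[1], are_hit$end[1])
  attr(s, "orientation") <- orientation_of(s, re_hit$start[1],
                                           are_hit$start[1])
  s
}

# Index of the ARE minimizing |spacer| for each RE, when all ARE hits share
# one width. |spacer| as a function of the start-sorted ARE index is the
# absolute value of a quasi-convex function, so its minima lie next to the
# three anchors below; candidates two indices either side of each anchor
# are guaranteed to cover them. Ties go to the lower-coordinate ARE.
nearest_are_const_width <- function(re_start, re_end, are_start, are_width) {
  n <- length(are_start)
  anchors <- cbind(re_end,
                   re_start - are_width,
                   (re_start + re_end - are_width) / 2)
  cand <- NULL
  for (k in seq_len(ncol(anchors))) {
    p <- findInterval(anchors[, k], are_start)
    cand <- cbind(cand, p - 2L, p - 1L, p, p + 1L, p + 2L)
  }
  cand[cand < 1L] <- 1L
  cand[cand > n] <- n
  best_abs <- rep(Inf, length(re_start))
  best_start <- rep(Inf, length(re_start))
  best_idx <- rep(NA_integer_, length(re_start))
  for (j in seq_len(ncol(cand))) {
    st <- are_start[cand[, j]]
    sp <- pmax(st - re_end, re_start - (st + are_width))
    a <- abs(sp)
    upd <- a < best_abs | (a == best_abs & st < best_start)
    best_abs[upd] <- a[upd]
    best_start[upd] <- st[upd]
    best_idx[upd] <- cand[upd, j]
  }
  best_idx
}

# Fallback for mixed ARE widths: per-RE brute force.
nearest_are_brute <- function(re_start, re_end, are_start, are_end) {
  vapply(seq_along(re_start), function(i) {
    sp <- interval_gap(re_start[i], re_end[i], are_start, are_end)
    a <- abs(sp)
    cand <- which(a == min(a))
    cand[which.min(are_start[cand])]
  }, integer(1))
}

#' Pair each RE hit with its nearest ARE hit
#'
#' RE-driven pairing: every RE with at least one ARE on its chromosome
#' within `max_window` is joined to the ARE minimizing the absolute spacer
#' (ties to the lower-coordinate ARE). AREs may serve several REs unless
#' `one_to_one = TRUE`, in which case AREs are assigned greedily in order of
#' increasing absolute spacer and displaced REs are re-paired with the
#' nearest remaining ARE. Strand is ignored for pairing; both strands are
#' recorded per pair.
#'
#' @param re_hits,are_hits motif-hit data.frames (see [scan_sequence()]).
#' @param max_window maximum absolute spacer to accept (default unlimited).
#' @param steric_threshold spacer must exceed this for `steric_ok` (bp).
#' @param one_to_one enforce strict one-to-one matching.
#' @return pair data.frame sorted by chrom then span_start with columns
#'   chrom, re_start, re_end, re_strand, are_start, are_end, are_strand,
#'   spacer, orientation, span_start, span_end, steric_ok.
#' @export
pair_nearest <- function(re_hits, are_hits, max_window = Inf,
                         steric_threshold = 7, one_to_one = FALSE) {
  empty <- data.frame(
    chrom = character(0), re_start = numeric(0), re_end = numeric(0),
    re_strand = character(0), are_start = numeric(0), are_end = numeric(0),
    are_strand = character(0), spacer = numeric(0),
    orientation = character(0), span_start = numeric(0),
    span_end = numeric(0), steric_ok = logical(0), stringsAsFactors = FALSE
  )
  if (is.null(re_hits) || nrow(re_hits) == 0 ||
      is.null(are_hits) || nrow(are_hits) == 0) {
    return(empty)
  }
  out <- list()
  for (ch in unique(re_hits$chrom)) {
    re <- re_hits[re_hits$chrom == ch, , drop = FALSE]
    are <- are_hits[are_hits$chrom == ch, , drop = FALSE]
    if (nrow(are) == 0) next
    are <- are[order(are$start, are$end), , drop = FALSE]
    widths <- unique(are$end - are$start)
    idx <- if (length(widths) == 1) {
      nearest_are_const_width(re$start, re$end, are$start, widths)
    } else {
      nearest_are_brute(re$start, re$end, are$start, are$end)
    }
    sp <- interval_gap(re$start, re$end, are$start[idx], are$end[idx])
    if (one_to_one) {
      sel <- resolve_one_to_one(re, are, idx, sp)
      idx <- sel$idx
      keep <- sel$keep
      re <- re[keep, , drop = FALSE]
      idx <- idx[keep]
      sp <- interval_gap(re$start, re$end, are$start[idx], are$end[idx])
    }
    out[[ch]] <- data.frame(
      chrom = re$chrom,
      re_start = re$start, re_end = re$end, re_strand = re$strand,
      are_start = are$start[idx], are_end = are$end[idx],
      are_strand = are$strand[idx],
      spacer = sp,
      orientation = orientation_of(sp, re$start, are$start[idx]),
      span_start = pmin(re$start, are$start[idx]),
      span_end = pmax(re$end, are$end[idx]),
      steric_ok = sp > steric_threshold,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(empty)
  pairs <- do.call(rbind, out)
  pairs <- pairs[abs(pairs$spacer) <= max_window, , drop = FALSE]
  pairs <- pairs[order(pairs$chrom, pairs$span_start, pairs$span_end), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# Greedy one-to-one assignment within one chromosome: process REs by
# ascending |spacer|; an RE whose nearest ARE is taken is re-paired against
# the remaining AREs until none are left.
resolve_one_to_one <- function(re, are, idx, sp) {
  n_re <- nrow(re)
  assigned_are <- rep(FALSE, nrow(are))
  final_idx <- rep(NA_integer_, n_re)
  pending <- order(abs(sp))
  cur_idx <- idx
  while (length(pending) > 0 && !all(assigned_are)) {
    retry <- integer(0)
    for (i in pending) {
      j <- cur_idx[i]
      if (!assigned_are[j]) {
        assigned_are[j] <- TRUE
        final_idx[i] <- j
      } else {
        retry <- c(retry, i)
      }
    }
    if (length(retry) == 0) break
    free <- which(!assigned_are)
    if (length(free) == 0) break
    sub <- nearest_are_brute(re$start[retry], re$end[retry],
                             are$start[free], are$end[free])
    cur_idx[retry] <- free[sub]
    sp_retry <- interval_gap(re$start[retry], re$end[retry],
                             are$start[free[sub]], are$end[free[sub]])
    pending <- retry[order(abs(sp_retry))]
  }
  list(idx = final_idx, keep = !is.na(final_idx))
}

#' Partition pairs by steric feasibility
#'
#' A pair is sterically feasible when its spacer strictly exceeds the
#' threshold (default 7 bp), the minimum inner gap that accommodates a p63
#' tetramer and an NRF2-small-MAF dimer side by side regardless of which
#' motif is upstream.
#'
#' @param pairs pair data.frame from [pair_nearest()].
#' @param threshold spacer threshold in bp.
#' @return list with `feasible` and `infeasible` pair tables (with
#'   `steric_ok` refreshed) and `counts` (named: feasible, infeasible).
#' @export
flag_steric <- function(pairs, threshold = 7) {
  pairs$steric_ok <- pairs$spacer > threshold
  list(
    feasible = pairs[pairs$steric_ok, , drop = FALSE],
    infeasible = pairs[!pairs$steric_ok, , drop = FALSE],
    counts = c(feasible = sum(pairs$steric_ok),
               infeasible = sum(!pairs$steric_ok))
  )
}

#' Extract pair sequences for motif-discovery tools
#'
#' One FASTA record per pair: the genomic slice covering both motifs plus
#' `flank` bases either side, clipped (with a warning) at chromosome ends.
#' Headers encode chromosome, span, spacer and orientation.
#'
#' @param pairs pair data.frame.
#' @param genome a `reare_genome` (or named character vector).
#' @param flank bases added on each side of the pair span.
#' @param path optional output FASTA path; written when non-NULL.
#' @return named character vector of sequences (names are headers);
#'   written to `path` as a side effect when requested.
#' @export
export_pair_sequences <- function(pairs, genome, flank = 0, path = NULL) {
  missing_chrom <- setdiff(unique(pairs$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    stop_usage("pair on unknown chromosome '%s'", missing_chrom[1])
  }
  if (nrow(pairs) == 0) {
    seqs <- character(0)
  } else {
    lens <- chrom_lengths(genome)[pairs$chrom]
    from <- pairs$span_start - flank
    to <- pairs$span_end + flank
    clipped <- from < 0 | to > lens
    if (any(clipped)) {
      warning(sprintf("%d pair sequence(s) clipped at chromosome ends",
                      sum(clipped)))
    }
    from <- pmax(from, 0)
    to <- pmin(to, lens)
    seqs <- substring(genome[pairs$chrom], from + 1, to)
    names(seqs) <- sprintf("%s:%.0f-%.0f|spacer=%.0f|%s",
                           pairs$chrom, from, to, pairs$spacer,
                           pairs$orientation)
  }
  if (!is.null(path)) write_fasta(seqs, path)
  seqs
}
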