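# ChIP-seq peak annotation: placing RE-ARE pairs under peaks, per-state
# percentages, unique/common peak set algebra across cell states, TSS
# distances, and closest-gene association.
#
# Interval work is done with IRanges; package coordinates are 0-based
# half-open and are converted to IRanges' 1-based closed convention at the
# call boundary.

iranges_of <- function(start0, end0) {
  IRanges::IRanges(start = as.integer(start0 + 1), end = as.integer(end0))
}

#' Containment interval of a peak
#'
#' Two conventions are supported: the reported peak range from the BED file
#' (default), or a fixed window of `half_width` bases either side of the
#' peak center (the 300-bp center convention used when peaks are defined by
#' read enrichment around their summit).
#'
#' @param peaks peak data.frame from [read_bed()].
#' @param mode `"reported_range"` or `"center_window"`.
#' @param half_width half-width in bases for `"center_window"`.
#' @return data.frame with columns `ci_start`, `ci_end` (0-based half-open),
#'   one row per peak.
#' @export
containment_interval <- function(peaks,
                                 mode = c("reported_range", "center_window"),
                                 half_width = 300) {
  mode <- match.arg(mode)
  if (mode == "reported_range") {
    data.frame(ci_start = peaks$start, ci_end = peaks$end)
  } else {
    data.frame(ci_start = pmax(peaks$center - half_width, 0),
               ci_end = peaks$center + half_width)
  }
}

#' Assign RE-ARE pairs to containing peaks
#'
#' A pair belongs to a peak iff both motif intervals lie fully inside the
#' peak's containment interval (equivalently, the pair span does). A pair
#' satisfying several overlapping peaks is assigned to each of them; such
#' multiple assignments are recorded so pair-level statistics can count the
#' pair once. When the underlying motif hit tables are supplied, peaks
#' carrying only a single motif class (RE-only or ARE-only) are flagged.
#'
#' @param pairs pair data.frame from [pair_nearest()].
#' @param peaks peak data.frame from [read_bed()].
#' @param mode,half_width see [containment_interval()].
#' @param re_hits,are_hits optional motif-hit tables used to count
#'   single-motif peaks.
#' @return object of class `reare_annotation`: list with `peaks` (the input
#'   peaks plus n_pairs, n_re_hits, n_are_hits, single_motif_only),
#'   `assignments` (peak_idx, pair_idx table) and `counts`
#'   (peaks_with_pairs, pairs_under_peaks, multiply_assigned_pairs,
#'   single_motif_peaks).
#' @export
pairs_under_peaks <- function(pairs, peaks,
                              mode = c("reported_range", "center_window"),
                              half_width = 300,
                              re_hits = NULL, are_hits = NULL) {
  mode <- match.arg(mode)
  ci <- containment_interval(peaks, mode = mode, half_width = half_width)
  n_peaks <- nrow(peaks)
  assignments <- data.frame(peak_idx = integer(0), pair_idx = integer(0))
  if (nrow(pairs) > 0 && n_peaks > 0) {
    hits_list <- lapply(unique(peaks$chrom), function(ch) {
      pk <- which(peaks$chrom == ch)
      pr <- which(pairs$chrom == ch)
      if (length(pk) == 0 || length(pr) == 0) return(NULL)
      ov <- IRanges::findOverlaps(
        iranges_of(pairs$span_start[pr], pairs$span_end[pr]),
        iranges_of(ci$ci_start[pk], ci$ci_end[pk]),
        type = "within"
      )
      data.frame(peak_idx = pk[S4Vectors::subjectHits(ov)],
                 pair_idx = pr[S4Vectors::queryHits(ov)])
    })
    assignments <- do.call(rbind, c(hits_list,
                                    list(assignments)))
    assignments <- assignments[order(assignments$peak_idx,
                                     assignments$pair_idx), , drop = FALSE]
    rownames(assignments) <- NULL
  }
  n_pairs_per_peak <- tabulate(assignments$peak_idx, nbins = n_peaks)
  count_contained_hits <- function(hits) {
    out <- integer(n_peaks)
    if (is.null(hits) || nrow(hits) == 0) return(out)
    for (ch in unique(peaks$chrom)) {
      pk <- which(peaks$chrom == ch)
      hi <- which(hits$chrom == ch)
      if (length(pk) == 0 || length(hi) == 0) next
      ov <- IRanges::findOverlaps(
        iranges_of(hits$start[hi], hits$end[hi]),
        iranges_of(ci$ci_start[pk], ci$ci_end[pk]),
        type = "within"
      )
      tab <- tabulate(S4Vectors::subjectHits(ov), nbins = length(pk))
      out[pk] <- out[pk] + tab
    }
    out
  }
  n_re <- count_contained_hits(re_hits)
  n_are <- count_contained_hits(are_hits)
  single_only <- n_pairs_per_peak == 0 & xor(n_re > 0, n_are > 0)
  annotated <- peaks
  annotated$n_pairs <- n_pairs_per_peak
  annotated$n_re_hits <- n_re
  annotated$n_are_hits <- n_are
  annotated$single_motif_only <- single_only
  structure(
    list(
      peaks = annotated,
      assignments = assignments,
      counts = c(
        peaks_with_pairs = sum(n_pairs_per_peak > 0),
        pairs_under_peaks = length(unique(assignments$pair_idx)),
        multiply_assigned_pairs =
          sum(table(assignments$pair_idx) > 1),
        single_motif_peaks = sum(single_only)
      )
    ),
    class = "reare_annotation"
  )
}

#' @export
print.reare_annotation <- function(x, ...) {
  cat("Peak annotation\n")
  cat(sprintf("  peaks: %d, with >= 1 contained RE-ARE pair: %d (%.2f%%)\n",
              nrow(x$peaks), x$counts[["peaks_with_pairs"]],
              100 * x$counts[["peaks_with_pairs"]] / max(nrow(x$peaks), 1)))
  cat(sprintf("  distinct pairs under peaks: %d (of which %d under > 1 peak)\n",
              x$counts[["pairs_under_peaks"]],
              x$counts[["multiply_assigned_pairs"]]))
  cat(sprintf("  single-motif-only peaks: %d\n",
              x$counts[["single_motif_peaks"]]))
  invisible(x)
}

#' Percentage of peaks containing RE-ARE pairs, per mark and state
#'
#' @param annotation a `reare_annotation` from [pairs_under_peaks()] whose
#'   peak table covers all peaks of interest (not only those with pairs).
#' @return data.frame with mark, state, n_peaks, n_with_pairs,
#'   n_pairs_total, percent_with_pairs.
#' @export
percentage_with_pairs <- function(annotation) {
  peaks <- annotation$peaks
  if (nrow(peaks) == 0) stop_usage("no peaks to compute percentages on")
  grp <- interaction(peaks$mark, peaks$state, drop = TRUE, sep = "/")
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    data.frame(
      mark = peaks$mark[sel][1], state = peaks$state[sel][1],
      n_peaks = sum(sel),
      n_with_pairs = sum(peaks$n_pairs[sel] > 0),
      n_pairs_total = sum(peaks$n_pairs[sel]),
      percent_with_pairs = 100 * sum(peaks$n_pairs[sel] > 0) / sum(sel),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Unique and common RE-ARE-containing peaks between two cell states
#'
#' Restricts each annotation to its RE-ARE-containing peaks, then calls a
#' peak in A "common" iff it overlaps (>= 1 bp, same chromosome, or at least
#' `min_overlap_fraction` of the shorter peak) any RE-ARE-containing peak in
#' B, and "unique" otherwise; symmetrically for B.
#'
#' @param annot_a,annot_b `reare_annotation` objects for the two states.
#' @param min_overlap_fraction minimum reciprocal overlap as a fraction of
#'   the shorter peak (0 = any single shared base, the default).
#' @return list with `unique_a`, `unique_b`, `common_a`, `common_b` peak
#'   tables and `counts`.
#' @export
peak_set_algebra <- function(annot_a, annot_b, min_overlap_fraction = 0) {
  a <- annot_a$peaks[annot_a$peaks$n_pairs > 0, , drop = FALSE]
  b <- annot_b$peaks[annot_b$peaks$n_pairs > 0, , drop = FALSE]
  common_flags <- function(x, y) {
    if (nrow(x) == 0) return(logical(0))
    if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
    flag <- rep(FALSE, nrow(x))
    for (ch in unique(x$chrom)) {
      xi <- which(x$chrom == ch)
      yi <- which(y$chrom == ch)
      if (length(yi) == 0) next
      ov <- IRanges::findOverlaps(iranges_of(x$start[xi], x$end[xi]),
                                  iranges_of(y$start[yi], y$end[yi]))
      if (length(ov) == 0) next
      qh <- S4Vectors::queryHits(ov)
      if (min_overlap_fraction > 0) {
        sh <- S4Vectors::subjectHits(ov)
        ov_len <- pmin(x$end[xi][qh], y$end[yi][sh]) -
          pmax(x$start[xi][qh], y$start[yi][sh])
        shorter <- pmin(x$end[xi][qh] - x$start[xi][qh],
                        y$end[yi][sh] - y$start[yi][sh])
        qh <- qh[ov_len >= min_overlap_fraction * shorter]
      }
      flag[xi[unique(qh)]] <- TRUE
    }
    flag
  }
  in_b <- common_flags(a, b)
  in_a <- common_flags(b, a)
  list(
    unique_a = a[!in_b, , drop = FALSE],
    unique_b = b[!in_a, , drop = FALSE],
    common_a = a[in_b, , drop = FALSE],
    common_b = b[in_a, , drop = FALSE],
    counts = c(n_a = nrow(a), n_b = nrow(b),
               unique_a = sum(!in_b), unique_b = sum(!in_a),
               common_a = sum(in_b), common_b = sum(in_a))
  )
}

#' Distance from each query to its nearest target
#'
#' Works in both directions: point queries (TSS) against interval targets
#' (pair spans), or interval queries against point targets. The distance is
#' 0 when the point lies within the span, otherwise the gap to the nearest
#' covered base of the span. Queries with no target on their chromosome are
#' reported separately.
#'
#' @param queries TSS data.frame (point queries, `position` column) or pair
#'   data.frame (interval queries, `span_start`/`span_end`).
#' @param targets pair data.frame or TSS data.frame, the opposite kind.
#' @return list with `distances` (one value per matched query),
#'   `query_idx` (row indices of matched queries) and `unmatched`
#'   (row indices of queries with no same-chromosome target).
#' @export
distance_to_nearest <- function(queries, targets) {
  as_points <- function(df) !is.null(df$position)
  if (as_points(queries)) {
    q_start <- queries$position
    q_end <- queries$position + 1
  } else {
    q_start <- queries$span_start
    q_end <- queries$span_end
  }
  if (as_points(targets)) {
    t_start <- targets$position
    t_end <- targets$position + 1
  } else {
    t_start <- targets$span_start
    t_end <- targets$span_end
  }
  if (length(q_start) == 0 || length(t_start) == 0) {
    stop_usage("queries and targets must be non-empty")
  }
  distances <- numeric(0)
  query_idx <- integer(0)
  unmatched <- integer(0)
  for (ch in unique(queries$chrom)) {
    qi <- which(queries$chrom == ch)
    ti <- which(targets$chrom == ch)
    if (length(ti) == 0) {
      unmatched <- c(unmatched, qi)
      next
    }
    qr <- iranges_of(q_start[qi], q_end[qi])
    tr <- iranges_of(t_start[ti], t_end[ti])
    # IRanges counts the bases strictly between ranges (adjacent = 0);
    # the pipeline's convention is the gap to the nearest covered base,
    # i.e. IRanges distance + 1 for disjoint ranges, 0 for overlap.
    dtn <- IRanges::distanceToNearest(qr, tr)
    d <- rep(NA_real_, length(qi))
    qh <- S4Vectors::queryHits(dtn)
    d[qh] <- S4Vectors::mcols(dtn)$distance
    overlaps <- IRanges::countOverlaps(qr, tr) > 0
    d <- ifelse(overlaps, 0, d + 1)
    distances <- c(distances, d)
    query_idx <- c(query_idx, qi)
  }
  ord <- order(query_idx)
  list(distances = distances[ord], query_idx = query_idx[ord],
       unmatched = sort(unmatched))
}

#' Associate RE-ARE-containing peaks with their closest gene
#'
#' For each peak with at least one contained pair, the TSS minimizing the
#' absolute distance to the peak center is assigned iff that distance is at
#' most `max_dist` (default 100 kb), following the closest-gene convention
#' of region-to-gene tools. With `duplicate_per_pair` the output holds one
#' row per (peak, contained pair), so a peak carrying two pairs lists its
#' gene twice. Peaks with no TSS in range are emitted with feature_id
#' `"unassigned"`.
#'
#' @param annotation a `reare_annotation` from [pairs_under_peaks()].
#' @param tss TSS data.frame from [read_tss_table()].
#' @param max_dist maximum |TSS - peak center| in bases.
#' @param duplicate_per_pair one output row per contained pair (default)
#'   rather than one per peak.
#' @return data.frame: chrom, peak_start, peak_end, peak_center, pair_idx,
#'   feature_id, source, distance (signed, TSS - center), assigned.
#' @export
associate_genes <- function(annotation, tss, max_dist = 100000,
                            duplicate_per_pair = TRUE) {
  if (nrow(tss) == 0) stop_usage("TSS table is empty")
  peaks <- annotation$peaks
  sel <- which(peaks$n_pairs > 0)
  rows <- lapply(sel, function(i) {
    cand <- which(tss$chrom == peaks$chrom[i])
    if (length(cand) > 0) {
      dd <- tss$position[cand] - peaks$center[i]
      best <- cand[order(abs(dd), tss$position[cand])[1]]
      dist <- tss$position[best] - peaks$center[i]
    }
    assigned <- length(cand) > 0 && abs(dist) <= max_dist
    n_rows <- if (duplicate_per_pair) peaks$n_pairs[i] else 1L
    pair_ids <- if (duplicate_per_pair) {
      annotation$assignments$pair_idx[annotation$assignments$peak_idx == i]
    } else {
      NA_integer_
    }
    data.frame(
      chrom = peaks$chrom[i], peak_start = peaks$start[i],
      peak_end = peaks$end[i], peak_center = peaks$center[i],
      pair_idx = pair_ids,
      feature_id = if (assigned) tss$feature_id[best] else "unassigned",
      source = if (assigned) tss$source[best] else NA_character_,
      distance = if (assigned) dist else NA_real_,
      assigned = assigned,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    chrom = character(0), peak_start = numeric(0), peak_end = numeric(0),
    peak_center = numeric(0), pair_idx = integer(0),
    feature_id = character(0), source = character(0),
    distance = numeric(0), assigned = logical(0), stringsAsFactors = FALSE
  ))))
  rownames(out) <- NULL
  out
}
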