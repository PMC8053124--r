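# Brute-force oracles and fixture builders, independent of the package's
# implementation paths (no Biostrings, no interval trees): plain per-window
# character-class tests and all-pairs minimizers.

# The oracle's own degenerate-code table (kept independent of the package).
ORACLE_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Per-position character-class matcher over every window, one strand:
# window i matches iff for every offset j the base at i+j is in the class
# of pattern position j.
oracle_scan_strand <- function(pattern, sequence, strand) {
  allowed <- ORACLE_CLASSES
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(pat)
  n <- length(chars)
  if (n < L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      strand = character(0)))
  }
  ok <- rep(TRUE, n - L + 1)
  for (j in seq_len(L)) {
    ok <- ok & chars[seq.int(j, n - L + j)] %in% allowed[[pat[j]]]
  }
  starts <- which(ok) - 1
  data.frame(start = starts, end = starts + L,
             strand = rep(strand, length(starts)))
}

# Both-strand oracle: forward pattern on '+', reverse-complement pattern
# (complement each code, reverse) on '-', coordinates on the forward strand.
oracle_scan <- function(motif, sequence, strands = "both") {
  out <- oracle_scan_strand(motif$pattern, sequence, "+")
  if (strands == "both") {
    out <- rbind(out,
                 oracle_scan_strand(motif$rc_pattern, sequence, "-"))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# All-pairs nearest-ARE minimizer with the documented tie rule
# (lower-coordinate ARE wins ties in |spacer|).
oracle_pair <- function(re_hits, are_hits) {
  rows <- list()
  for (i in seq_len(nrow(re_hits))) {
    sel <- which(are_hits$chrom == re_hits$chrom[i])
    if (length(sel) == 0) next
    sp <- pmax(are_hits$start[sel] - re_hits$end[i],
               re_hits$start[i] - are_hits$end[sel])
    best <- sel[order(abs(sp), are_hits$start[sel])[1]]
    rows[[length(rows) + 1]] <- data.frame(
      re_start = re_hits$start[i], re_end = re_hits$end[i],
      are_start = are_hits$start[best], are_end = are_hits$end[best],
      spacer = pmax(are_hits$start[best] - re_hits$end[i],
                    re_hits$start[i] - are_hits$end[best])
    )
  }
  if (length(rows) == 0) {
    return(data.frame(re_start = numeric(0), re_end = numeric(0),
                      are_start = numeric(0), are_end = numeric(0),
                      spacer = numeric(0)))
  }
  do.call(rbind, rows)
}

# Brute-force sup of |F_a - F_b| over all pooled sample points.
oracle_ks_d <- function(a, b) {
  z <- c(a, b)
  d <- 0
  for (x in z) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# Brute-force nearest distance between point queries and interval targets
# (0 inside; otherwise gap to the nearest covered base).
oracle_point_to_span <- function(pos, chrom, span_df) {
  vapply(seq_along(pos), function(i) {
    sel <- which(span_df$chrom == chrom[i])
    if (length(sel) == 0) return(NA_real_)
    min(pmax(0, span_df$span_start[sel] - pos[i],
             pos[i] - span_df$span_end[sel] + 1))
  }, numeric(1))
}

# Random hit table on a set of chromosomes.
random_hits <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                        width_range = c(5, 25), motif = "X") {
  ch <- sample(chroms, n, replace = TRUE)
  st <- floor(runif(n, 0, max_pos))
  w <- floor(runif(n, width_range[1], width_range[2] + 1))
  data.frame(chrom = ch, start = st, end = st + w,
             strand = sample(c("+", "-"), n, replace = TRUE),
             motif = motif, seq = NA_character_, stringsAsFactors = FALSE)
}

# A single motif-hit row.
hit_row <- function(chrom, start, end, strand = "+", motif = "X") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             motif = motif, seq = NA_character_, stringsAsFactors = FALSE)
}

# A peak table from coordinate triples.
peak_table <- function(chrom, start, end, mark = "H3K27ac",
                       state = "other") {
  data.frame(chrom = chrom, start = start, end = end,
             center = floor((start + end) / 2),
             name = sprintf("peak_%d", seq_along(start)),
             mark = mark, state = state, stringsAsFactors = FALSE)
}

# Random degenerate motifs for oracle-equivalence runs.
random_iupac_motif <- function(name, len) {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")
  # bias toward concrete bases so hits exist but are not everywhere
  probs <- c(rep(3, 4), rep(1, 6), 0.5)
  rearescan::compile_motif(
    name, paste(sample(codes, len, replace = TRUE, prob = probs),
                collapse = "")
  )
}

random_dna <- function(n, with_n = TRUE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  probs <- if (with_n) c(rep(0.2425, 4), 0.03) else rep(0.25, 4)
  paste(sample(alph, n, replace = TRUE, prob = probs), collapse = "")
}
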