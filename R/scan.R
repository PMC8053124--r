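# Degenerate-consensus scanning of genome sequences.
#
# Matching is exact IUPAC matching via Biostrings; minus-strand hits are
# found by matching the reverse-complement pattern against the forward
# strand, so all coordinates stay on the forward strand. Assembly gaps (N)
# never produce hits: Biostrings would let a pattern N match a subject N,
# so windows whose genomic substring contains N are filtered out.

scan_one_strand <- function(pattern, sequence, subject) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                fixed = "subject")
  starts <- BiocGenerics::start(m)
  if (length(starts) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  ends <- BiocGenerics::end(m)
  seqs <- substring(sequence, starts, ends)
  keep <- !grepl("N", seqs, fixed = TRUE)
  data.frame(start = as.numeric(starts[keep]) - 1,
             end = as.numeric(ends[keep]),
             seq = seqs[keep], stringsAsFactors = FALSE)
}

#' Scan one chromosome sequence for a degenerate motif
#'
#' Reports every window whose bases all satisfy the motif's per-position
#' IUPAC classes. Forward matches are '+' hits; windows matching the
#' reverse-complement pattern are '-' hits at the same forward-strand
#' coordinates. Overlapping hits are all reported, and a window matching on
#' both strands (palindromic match) yields two hits unless `dedup = TRUE`.
#'
#' @param motif an [compile_motif()] object.
#' @param sequence chromosome sequence (string over `{A,C,G,T,N}`).
#' @param chrom chromosome name to record on each hit.
#' @param strands `"both"` (default) or `"+"`.
#' @param dedup collapse same-interval hits across strands, keeping '+'.
#' @return hit data.frame: chrom, start, end (0-based half-open), strand,
#'   motif, seq (forward-strand genomic substring), sorted by start then
#'   strand.
#' @export
scan_sequence <- function(motif, sequence, chrom = "chr",
                          strands = c("both", "+"), dedup = FALSE) {
  strands <- match.arg(strands)
  if (!inherits(motif, "iupac_motif")) {
    stop_usage("motif must be compiled with compile_motif()")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) < motif$length) return(empty_hits())
  subject <- Biostrings::DNAString(sequence)
  fwd <- scan_one_strand(motif$pattern, sequence, subject)
  hits <- data.frame(chrom = rep(chrom, nrow(fwd)), start = fwd$start,
                     end = fwd$end, strand = rep("+", nrow(fwd)),
                     motif = rep(motif$name, nrow(fwd)), seq = fwd$seq,
                     stringsAsFactors = FALSE)
  if (strands == "both") {
    rev <- scan_one_strand(motif$rc_pattern, sequence, subject)
    hits <- rbind(hits, data.frame(
      chrom = rep(chrom, nrow(rev)), start = rev$start, end = rev$end,
      strand = rep("-", nrow(rev)), motif = rep(motif$name, nrow(rev)),
      seq = rev$seq, stringsAsFactors = FALSE
    ))
  }
  if (dedup && nrow(hits) > 0) {
    hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
    hits <- hits[!duplicated(hits[c("start", "end")]), , drop = FALSE]
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a genome for a set of motifs
#'
#' @param motifs list of [compile_motif()] objects with unique names.
#' @param genome a `reare_genome` (or named character vector of sequences).
#' @param strands `"both"` (default) or `"+"`.
#' @param dedup collapse palindromic same-interval double hits.
#' @return an object of class `reare_scan`: list with `hits` (one table,
#'   all motifs), `counts` (per chromosome x motif) and `totals` (named
#'   per-motif totals).
#' @export
scan_genome <- function(motifs, genome, strands = c("both", "+"),
                        dedup = FALSE) {
  strands <- match.arg(strands)
  if (inherits(motifs, "iupac_motif")) motifs <- list(motifs)
  if (length(motifs) == 0) stop_usage("need at least one motif")
  motif_names <- vapply(motifs, `[[`, character(1), "name")
  if (anyDuplicated(motif_names)) stop_usage("duplicate motif names")
  if (length(genome) == 0) stop_usage("need at least one chromosome")
  per <- vector("list", length(motifs) * length(genome))
  k <- 0
  for (m in motifs) {
    for (nm in names(genome)) {
      k <- k + 1
      per[[k]] <- scan_sequence(m, genome[[nm]], chrom = nm,
                                strands = strands, dedup = dedup)
    }
  }
  hits <- do.call(rbind, per)
  rownames(hits) <- NULL
  counts <- as.data.frame.matrix(table(
    factor(hits$chrom, levels = names(genome)),
    factor(hits$motif, levels = motif_names)
  ))
  counts <- cbind(chrom = rownames(counts), counts)
  rownames(counts) <- NULL
  totals <- vapply(motif_names, function(mn) sum(hits$motif == mn), numeric(1))
  structure(list(hits = hits, counts = counts, totals = totals),
            class = "reare_scan")
}

#' @export
print.reare_scan <- function(x, ...) {
  cat("Genome-wide motif scan\n")
  for (mn in names(x$totals)) {
    cat(sprintf("  %s: %.0f hits\n", mn, x$totals[[mn]]))
  }
  cat(sprintf("  chromosomes: %d\n", nrow(x$counts)))
  invisible(x)
}
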