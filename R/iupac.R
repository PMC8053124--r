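# IUPAC degenerate nucleotide alphabet and motif compilation.
#
# Transcription-factor consensus sites (the p63 RE and the NRF2 ARE) are
# expressed as IUPAC strings; matching is exact degenerate-consensus
# matching, not PWM scoring.

# Allowed concrete bases per IUPAC code. N expands to {A,C,G,T}: an N in a
# *pattern* matches any real base, but an N in the *genome* is an assembly
# gap and matches nothing (it is not in any allowed set).
IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B",
  D = "H", H = "D", N = "N"
)

#' Reverse complement of an IUPAC pattern
#'
#' Complements each degenerate code (R <-> Y, K <-> M, B <-> V, D <-> H;
#' S, W, N are self-complementary) and reverses the string.
#'
#' @param pattern a string over the IUPAC nucleotide alphabet.
#' @return the reverse-complement IUPAC string.
#' @examples
#' reverse_complement_pattern("TGACNNNGC")
#' @export
reverse_complement_pattern <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_COMPLEMENT))
  if (length(bad) > 0) {
    stop_usage("illegal IUPAC code '%s' at position %d", chars[bad[1]], bad[1])
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Compile an IUPAC consensus string into a motif object
#'
#' Validates the pattern, builds the per-position allowed-base table used by
#' the scanner and the brute-force realizer, and precomputes the
#' reverse-complement pattern for minus-strand scanning.
#'
#' @param name motif label (e.g. "RE", "ARE").
#' @param pattern consensus string over the IUPAC codes
#'   `A C G T R Y S W K M B D H V N`.
#' @return an object of class `iupac_motif` with elements `name`, `pattern`,
#'   `length`, `allowed` (list of character vectors, one per position) and
#'   `rc_pattern`.
#' @examples
#' compile_motif("ARE", "TGACNNNGC")
#' @export
compile_motif <- function(name, pattern) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_usage("motif name must be a non-empty string")
  }
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    stop_usage("motif pattern must be a non-empty string")
  }
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_BASES))
  if (length(bad) > 0) {
    stop_usage("motif '%s': illegal IUPAC code '%s' at position %d",
               name, chars[bad[1]], bad[1])
  }
  if (length(chars) < 2L) {
    stop_usage("motif '%s': pattern must be at least 2 bases long", name)
  }
  structure(
    list(
      name = name,
      pattern = pattern,
      length = length(chars),
      allowed = unname(IUPAC_BASES[chars]),
      rc_pattern = reverse_complement_pattern(pattern)
    ),
    class = "iupac_motif"
  )
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("IUPAC motif '%s': %s (%d bp; reverse complement %s)\n",
              x$name, x$pattern, x$length, x$rc_pattern))
  invisible(x)
}

#' Read a motif configuration table
#'
#' Each non-comment line holds `name<TAB>IUPAC_pattern`. The exact RE and
#' ARE consensus strings are configuration inputs, supplied by the user.
#'
#' @param path path to the tab-separated motif file.
#' @return a named list of [compile_motif()] objects.
#' @export
read_motif_table <- function(path) {
  if (!file.exists(path)) stop_usage("motif file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop_format("motif file '%s' has no entries", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  motifs <- lapply(fields, function(f) {
    if (length(f) < 2) stop_format("motif line needs name<TAB>pattern")
    compile_motif(f[[1]], f[[2]])
  })
  names(motifs) <- vapply(motifs, `[[`, character(1), "name")
  if (anyDuplicated(names(motifs))) {
    stop_usage("duplicate motif names in %s", path)
  }
  motifs
}

#' Default placeholder motifs
#'
#' Documented placeholder consensus strings for the p63 response element
#' (two canonical p53-family half sites, RRRCWWGYYY x 2) and the NRF2
#' antioxidant response element core (TGACNNNGC). These are stand-ins with
#' realistic information content: reproducing published genome-wide totals
#' requires supplying the study-specific consensus strings via
#' [read_motif_table()].
#'
#' @return named list with compiled `RE` and `ARE` motifs.
#' @export
default_motifs <- function() {
  list(
    RE = compile_motif("RE", "RRRCWWGYYYRRRCWWGYYY"),
    ARE = compile_motif("ARE", "TGACNNNGC")
  )
}
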