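# Reading and writing the standard formats the pipeline touches.
#
# Every coordinate in this package is 0-based, half-open (BED-native).
# Dialects with 1-based positions are converted at the boundary.

#' Construct a genome object from named sequences
#'
#' @param x named character vector of nucleotide sequences over
#'   `{A,C,G,T,N}` (case-insensitive; `U` is mapped to `T`).
#' @return an object of class `reare_genome`: a named uppercase character
#'   vector, one element per chromosome.
#' @export
as_genome <- function(x) {
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop_usage("a genome is a named character vector of sequences")
  }
  if (anyDuplicated(names(x))) stop_usage("duplicate chromosome names")
  x <- chartr("u", "T", toupper(x))
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop_format("chromosome '%s' contains characters outside {A,C,G,T,N}",
                names(x)[which(bad)[1]])
  }
  structure(x, class = "reare_genome")
}

#' Chromosome lengths of a genome
#' @param genome a `reare_genome` object (or named character vector).
#' @return named numeric vector of sequence lengths in bases.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(as.numeric(nchar(genome)), names(genome))
}

#' @export
print.reare_genome <- function(x, ...) {
  cat(sprintf("Genome with %d chromosome(s), %.0f bp total\n",
              length(x), sum(nchar(x))))
  for (nm in names(x)) cat(sprintf("  %s: %d bp\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Sequences are upper-cased (soft-masked bases are treated as normal
#' sequence), `U` is mapped to `T`, and any character outside `{A,C,G,T,N}`
#' is rejected with the offending line number.
#'
#' @param path FASTA file path.
#' @return a `reare_genome` object; record order follows the file.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot open FASTA file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) stop_format("empty FASTA file: %s", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop_format("FASTA must start with a '>' header (%s)", path)
  seq_lines <- toupper(lines[!hdr])
  seq_lines <- gsub("U", "T", seq_lines, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seq_lines)
  if (any(bad)) {
    line_no <- which(!hdr)[which(bad)[1]]
    stop_format("illegal sequence character at line %d of %s", line_no, path)
  }
  rec_id <- cumsum(hdr)
  names_raw <- sub("^>\\s*", "", lines[hdr])
  names_clean <- sub("\\s.*$", "", names_raw)
  if (any(!nzchar(names_clean))) stop_format("empty FASTA record name")
  if (anyDuplicated(names_clean)) {
    stop_format("duplicate FASTA record name '%s'",
                names_clean[which(duplicated(names_clean))[1]])
  }
  seqs <- vapply(
    seq_along(names_clean),
    function(i) paste(seq_lines[rec_id[!hdr] == i], collapse = ""),
    character(1)
  )
  names(seqs) <- names_clean
  as_genome(seqs)
}

#' Write a genome to a FASTA file
#'
#' @param genome a `reare_genome` (or named character vector).
#' @param path output file path.
#' @param width bases per sequence line.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    n <- nchar(s)
    if (n == 0) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read ChIP-seq peak intervals from a BED file
#'
#' BED convention: 0-based, half-open, at least three tab-separated columns
#' (chrom, start, end). The peak center is `floor((start + end) / 2)`.
#'
#' @param path BED file path.
#' @param mark ChIP mark label attached to every peak (e.g. "H3K27ac").
#' @param state cell-state label attached to every peak (e.g. "KP", "DK").
#' @return data.frame with columns chrom, start, end, center, name, mark,
#'   state, ordered as in the file.
#' @export
read_bed <- function(path, mark = "other", state = "other") {
  if (!file.exists(path)) stop("cannot open BED file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), center = numeric(0),
                      name = character(0), mark = character(0),
                      state = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_format("line %d of %s: BED needs >= 3 columns",
                line_no[which(nf < 3)[1]], path)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_chr <- vapply(fields, `[[`, character(1), 2L)
  end_chr <- vapply(fields, `[[`, character(1), 3L)
  if (any(!grepl("^-?[0-9]+$", c(start_chr, end_chr)))) {
    bad <- which(!grepl("^[0-9]+$", start_chr) | !grepl("^[0-9]+$", end_chr))[1]
    stop_format("line %d of %s: non-integer coordinates", line_no[bad], path)
  }
  start <- as.numeric(start_chr)
  end <- as.numeric(end_chr)
  if (any(start < 0)) {
    stop_format("line %d of %s: negative start",
                line_no[which(start < 0)[1]], path)
  }
  if (any(end <= start)) {
    stop_format("line %d of %s: end <= start",
                line_no[which(end <= start)[1]], path)
  }
  nm <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 4) fields[[i]][[4L]] else sprintf("peak_%d", i)
  }, character(1))
  data.frame(chrom = chrom, start = start, end = end,
             center = floor((start + end) / 2), name = nm,
             mark = mark, state = state, stringsAsFactors = FALSE)
}

#' Read a TSS table
#'
#' Tab-separated columns: feature_id, chrom, position, strand. Positions are
#' 0-based by default; 1-based browser-style dialects are supported via
#' `one_based = TRUE`, which subtracts 1 at the boundary.
#'
#' @param path TSS table path ('#'-prefixed comment lines ignored).
#' @param source provenance tag, "gene" or "mirna".
#' @param one_based set TRUE if the file's positions are 1-based.
#' @return data.frame with columns feature_id, chrom, position, strand,
#'   source.
#' @export
read_tss_table <- function(path, source = c("gene", "mirna"),
                           one_based = FALSE) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("cannot open TSS table: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(data.frame(feature_id = character(0), chrom = character(0),
                      position = numeric(0), strand = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop_format("line %d of %s: TSS table needs 4 columns",
                line_no[which(nf < 4)[1]], path)
  }
  feature_id <- vapply(fields, `[[`, character(1), 1L)
  chrom <- vapply(fields, `[[`, character(1), 2L)
  pos_chr <- vapply(fields, `[[`, character(1), 3L)
  strand <- vapply(fields, `[[`, character(1), 4L)
  if (any(!grepl("^-?[0-9]+$", pos_chr))) {
    stop_format("line %d of %s: non-integer TSS position",
                line_no[which(!grepl("^-?[0-9]+$", pos_chr))[1]], path)
  }
  position <- as.numeric(pos_chr)
  if (one_based) position <- position - 1
  if (any(position < 0)) {
    stop_format("line %d of %s: negative TSS position",
                line_no[which(position < 0)[1]], path)
  }
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop_format("line %d of %s: strand must be '+' or '-'",
                line_no[which(bad_strand)[1]], path)
  }
  data.frame(feature_id = feature_id, chrom = chrom, position = position,
             strand = strand, source = source, stringsAsFactors = FALSE)
}

# Deterministic row order for all written tables.
sort_genomic <- function(df, start_col = "start", end_col = "end") {
  df[order(df$chrom, df[[start_col]], df[[end_col]]), , drop = FALSE]
}

#' Write pipeline records to disk
#'
#' Writes a homogeneous record table either as a tab-separated report with a
#' '#'-prefixed header line, or (for motif hits, pairs and peaks) as BED.
#' Rows are sorted by chrom, start, end so output is deterministic.
#'
#' @param records a data.frame of one record type (hits, pairs, peaks, TSS,
#'   or any report table with chrom/start/end columns for BED output).
#' @param path output file path.
#' @param format "tsv" or "bed".
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) {
    stop_usage("records must be a single homogeneous data.frame")
  }
  if (format == "bed") {
    if (is_hits_df(records)) {
      df <- sort_genomic(records)
      bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                        name = df$motif, score = 0L, strand = df$strand)
    } else if (is_pairs_df(records)) {
      df <- records[order(records$chrom, records$span_start,
                          records$span_end), , drop = FALSE]
      bed <- data.frame(chrom = df$chrom, start = df$span_start,
                        end = df$span_end,
                        name = sprintf("RE-ARE|spacer=%.0f|%s",
                                       df$spacer, df$orientation),
                        score = 0L, strand = ".")
    } else if (is_peaks_df(records)) {
      df <- sort_genomic(records)
      bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                        name = df$name, score = 0L, strand = ".")
    } else {
      stop_usage("BED output supported for motif hits, pairs and peaks only")
    }
    if (nrow(bed) > 0) {
      utils::write.table(format(bed, scientific = FALSE, trim = TRUE),
                         path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      file.create(path)
    }
  } else {
    df <- records
    if (is_hits_df(df) || is_peaks_df(df)) df <- sort_genomic(df)
    if (is_pairs_df(df)) {
      df <- df[order(df$chrom, df$span_start, df$span_end), , drop = FALSE]
    }
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
    if (nrow(df) > 0) {
      utils::write.table(format(df, scientific = FALSE, trim = TRUE),
                         con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output file path.
#' @param width bases per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  write_genome_fasta(seqs, path, width = width)
}
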