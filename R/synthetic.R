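# Synthetic test worlds: genomes with planted RE-ARE pairs at controlled
# spacers, decoy motifs, matching peak files and TSS tables, plus a
# machine-readable truth table, so the whole pipeline is testable without
# any external download.

#' Configure a synthetic world
#'
#' @param chrom_lengths named vector of chromosome lengths (bases).
#' @param gc_content background GC fraction in (0, 1).
#' @param n_planted_pairs number of RE-ARE pairs to plant.
#' @param spacer list describing the spacer distribution:
#'   `list(kind = "fixed", k =)`, `list(kind = "uniform", min =, max =)`, or
#'   `list(kind = "normal", mean =, sd =)` (normal draws are rounded and
#'   truncated at 0).
#' @param n_decoy_re,n_decoy_are lone decoy motif instances scattered
#'   uniformly outside planted elements.
#' @param peak_coverage fraction of planted pairs covered by an emitted peak.
#' @param peak_padding bases added either side of a covered pair span.
#' @param n_background_peaks extra peaks over empty background.
#' @param background_peak_width width of background peaks (bases).
#' @param n_tss number of TSS records to emit.
#' @param tss_distance list describing TSS placement relative to planted
#'   pair spans, same kinds as `spacer`.
#' @param exclude_background re-draw background windows that happen to match
#'   either motif, so the truth table is exact (default TRUE).
#' @param seed master integer seed.
#' @return object of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(chrom_lengths = c(chr1 = 1e6),
                                   gc_content = 0.41,
                                   n_planted_pairs = 50,
                                   spacer = list(kind = "normal",
                                                 mean = 100, sd = 10),
                                   n_decoy_re = 20, n_decoy_are = 100,
                                   peak_coverage = 0.5, peak_padding = 100,
                                   n_background_peaks = 0,
                                   background_peak_width = 600,
                                   n_tss = 20,
                                   tss_distance = list(kind = "uniform",
                                                       min = 0, max = 50000),
                                   exclude_background = TRUE,
                                   seed = 1L) {
  if (gc_content <= 0 || gc_content >= 1) {
    stop_usage("gc_content must be in (0, 1)")
  }
  if (peak_coverage < 0 || peak_coverage > 1) {
    stop_usage("peak_coverage must be in [0, 1]")
  }
  structure(
    list(chrom_lengths = chrom_lengths, gc_content = gc_content,
         n_planted_pairs = n_planted_pairs, spacer = spacer,
         n_decoy_re = n_decoy_re, n_decoy_are = n_decoy_are,
         peak_coverage = peak_coverage, peak_padding = peak_padding,
         n_background_peaks = n_background_peaks,
         background_peak_width = background_peak_width,
         n_tss = n_tss, tss_distance = tss_distance,
         exclude_background = exclude_background,
         seed = as.integer(seed)),
    class = "synthetic_world_config"
  )
}

draw_from_spec <- function(spec, n) {
  if (n == 0) return(numeric(0))
  switch(spec$kind,
    fixed = rep(spec$k, n),
    uniform = floor(stats::runif(n, spec$min, spec$max + 1)),
    normal = pmax(round(stats::rnorm(n, spec$mean, spec$sd)), 0),
    stop_usage("unknown distribution kind '%s'", spec$kind)
  )
}

#' Realize one concrete instance of a degenerate motif
#'
#' Each position is drawn uniformly from the bases allowed by the motif's
#' IUPAC code at that position, so the instance matches the motif by
#' construction.
#'
#' @param motif an [compile_motif()] object.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return nucleotide string of motif length.
#' @export
realize_motif_instance <- function(motif, seed = NULL) {
  draw <- function() {
    paste(vapply(motif$allowed,
                 function(b) if (length(b) == 1) b else sample(b, 1),
                 character(1)), collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate random background sequence free of given motifs
#'
#' Bases are i.i.d. with the requested expected GC content. When
#' `forbidden_motifs` are given, any window matching one of them (either
#' strand) is re-drawn until the sequence is clean or the retry cap is hit;
#' a cap hit leaves residual matches and raises a warning.
#'
#' @param length sequence length (bases, >= 0).
#' @param gc_content expected GC fraction.
#' @param forbidden_motifs list of [compile_motif()] objects to exclude.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @param max_iter redraw passes before giving up.
#' @return nucleotide string.
#' @export
generate_background <- function(length, gc_content = 0.41,
                                forbidden_motifs = list(), seed = NULL,
                                max_iter = 20L) {
  for (m in forbidden_motifs) {
    if (all(vapply(m$allowed, function(b) base::length(b) == 4, logical(1)))) {
      stop_usage("cannot exclude motif '%s': it matches every window", m$name)
    }
  }
  gen <- function() {
    if (length == 0) return("")
    probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
               G = gc_content / 2, T = (1 - gc_content) / 2)
    chars <- sample(names(probs), length, replace = TRUE, prob = probs)
    s <- paste(chars, collapse = "")
    if (base::length(forbidden_motifs) > 0) {
      for (it in seq_len(max_iter)) {
        hits <- do.call(rbind, lapply(forbidden_motifs, function(m) {
          scan_sequence(m, s, strands = "both")
        }))
        if (is.null(hits) || nrow(hits) == 0) return(s)
        redraw <- unique(hits[c("start", "end")])
        for (r in seq_len(nrow(redraw))) {
          span <- (redraw$start[r] + 1):redraw$end[r]
          chars[span] <- sample(names(probs), base::length(span),
                                replace = TRUE, prob = probs)
        }
        s <- paste(chars, collapse = "")
      }
      hits <- do.call(rbind, lapply(forbidden_motifs, function(m) {
        scan_sequence(m, s, strands = "both")
      }))
      if (!is.null(hits) && nrow(hits) > 0) {
        warning(sprintf("background exclusion cap hit: %d residual match(es)",
                        nrow(hits)))
      }
    }
    s
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Inserting motif instances into a clean background can create fresh
# matches across insert junctions. Redraw the unprotected bases of any
# match window that is not an exact planted interval until the sequence is
# clean (or the cap is hit).
scrub_stray_matches <- function(sequence, motifs, protected, gc_content,
                                seed, max_iter = 10L) {
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
  prot_key <- character(0)
  prot_mask <- rep(FALSE, nchar(sequence))
  if (!is.null(protected) && nrow(protected) > 0) {
    prot_key <- paste(protected$start, protected$end)
    for (r in seq_len(nrow(protected))) {
      prot_mask[(protected$start[r] + 1):protected$end[r]] <- TRUE
    }
  }
  with_seed(seed, {
    chars <- NULL
    for (it in seq_len(max_iter)) {
      hits <- do.call(rbind, lapply(motifs, function(m) {
        scan_sequence(m, sequence, strands = "both")
      }))
      stray <- hits[!paste(hits$start, hits$end) %in% prot_key, ,
                    drop = FALSE]
      if (nrow(stray) == 0) return(sequence)
      if (is.null(chars)) chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
      for (r in seq_len(nrow(stray))) {
        span <- (stray$start[r] + 1):stray$end[r]
        span <- span[!prot_mask[span]]
        if (length(span) > 0) {
          chars[span] <- sample(names(probs), length(span), replace = TRUE,
                                prob = probs)
        }
      }
      sequence <- paste(chars, collapse = "")
    }
    warning("stray motif matches remain after scrub cap")
    sequence
  })
}

# Sample `count` non-overlapping interval starts of the given widths on
# [0, len), keeping a guard gap around each, avoiding `occupied` (two-column
# matrix of start/end). Rejection sampling with a cap.
sample_free_starts <- function(len, widths, occupied, guard = 10,
                               max_retry = 1000L) {
  starts <- numeric(0)
  occ <- occupied
  for (w in widths) {
    placed <- FALSE
    for (r in seq_len(max_retry)) {
      s <- floor(stats::runif(1, 0, len - w + 1))
      if (is.null(occ) || nrow(occ) == 0 ||
          all(s + w + guard <= occ[, 1] | s >= occ[, 2] + guard)) {
        occ <- rbind(occ, c(s, s + w))
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("simulation error: could not place an element of width ", w,
           " without overlap; chromosome too crowded", call. = FALSE)
    }
  }
  list(starts = starts, occupied = occ)
}

#' Generate a synthetic world with known ground truth
#'
#' Builds chromosomes of background sequence (optionally free of incidental
#' RE/ARE matches), plants `n_planted_pairs` RE-ARE elements at spacers
#' drawn from the configured distribution with the RE/ARE order randomized
#' 50/50 per pair, scatters lone decoy motifs, emits peaks over a configured
#' fraction of pairs (pair span plus padding) plus optional background
#' peaks, and places TSS at configured distances from planted pair spans.
#'
#' @param config a [synthetic_world_config()].
#' @param re_motif,are_motif compiled motifs (defaults from
#'   [default_motifs()]).
#' @return object of class `synthetic_world`: list with `genome`, `truth`
#'   (element kind, coordinates, intended spacer/distance), `peaks`, `tss`
#'   and `config`.
#' @export
plant_world <- function(config, re_motif = default_motifs()$RE,
                        are_motif = default_motifs()$ARE) {
  stopifnot(inherits(config, "synthetic_world_config"))
  lens <- config$chrom_lengths
  n_chrom <- length(lens)
  pair_alloc <- allocate_counts(lens, config$n_planted_pairs)
  decoy_re_alloc <- allocate_counts(lens, config$n_decoy_re)
  decoy_are_alloc <- allocate_counts(lens, config$n_decoy_are)
  forbidden <- if (config$exclude_background) {
    list(re_motif, are_motif)
  } else {
    list()
  }
  genome <- character(n_chrom)
  names(genome) <- names(lens)
  truth_rows <- list()
  for (i in seq_len(n_chrom)) {
    ch <- names(lens)[i]
    len <- lens[[i]]
    seq_chr <- generate_background(len, config$gc_content,
                                   forbidden_motifs = forbidden,
                                   seed = derive_seed(config$seed, i, 10L))
    chars <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
    occ <- NULL
    with_seed(derive_seed(config$seed, i, 11L), {
      n_pairs <- pair_alloc[[i]]
      spacers <- draw_from_spec(config$spacer, n_pairs)
      re_first <- stats::runif(n_pairs) < 0.5
      widths <- re_motif$length + are_motif$length + spacers
      if (n_pairs > 0) {
        placed <- sample_free_starts(len, widths, occ,
                                     guard = config$peak_padding + 10)
        occ <- placed$occupied
        for (k in seq_len(n_pairs)) {
          s <- placed$starts[k]
          re_seq <- realize_motif_instance(re_motif)
          are_seq <- realize_motif_instance(are_motif)
          if (re_first[k]) {
            re_start <- s
            are_start <- s + re_motif$length + spacers[k]
          } else {
            are_start <- s
            re_start <- s + are_motif$length + spacers[k]
          }
          chars[(re_start + 1):(re_start + re_motif$length)] <-
            strsplit(re_seq, "", fixed = TRUE)[[1]]
          chars[(are_start + 1):(are_start + are_motif$length)] <-
            strsplit(are_seq, "", fixed = TRUE)[[1]]
          truth_rows[[length(truth_rows) + 1]] <- data.frame(
            kind = "planted_pair", chrom = ch,
            start = s, end = s + widths[k],
            re_start = re_start, re_end = re_start + re_motif$length,
            are_start = are_start, are_end = are_start + are_motif$length,
            spacer = spacers[k],
            orientation = if (re_first[k]) "RE_upstream" else "ARE_upstream",
            stringsAsFactors = FALSE
          )
        }
      }
      for (kind in c("decoy_re", "decoy_are")) {
        n_dec <- if (kind == "decoy_re") decoy_re_alloc[[i]]
                 else decoy_are_alloc[[i]]
        m <- if (kind == "decoy_re") re_motif else are_motif
        if (n_dec > 0) {
          placed <- sample_free_starts(len, rep(m$length, n_dec), occ,
                                       guard = config$peak_padding + 10)
          occ <- placed$occupied
          for (s in placed$starts) {
            inst <- realize_motif_instance(m)
            chars[(s + 1):(s + m$length)] <- strsplit(inst, "",
                                                      fixed = TRUE)[[1]]
            truth_rows[[length(truth_rows) + 1]] <- data.frame(
              kind = kind, chrom = ch, start = s, end = s + m$length,
              re_start = NA_real_, re_end = NA_real_,
              are_start = NA_real_, are_end = NA_real_,
              spacer = NA_real_, orientation = NA_character_,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    })
    seq_final <- paste(chars, collapse = "")
    if (config$exclude_background && length(forbidden) > 0) {
      tr <- do.call(rbind, truth_rows)
      if (is.null(tr)) {
        protected <- data.frame(start = numeric(0), end = numeric(0))
      } else {
        tr <- tr[tr$chrom == ch, , drop = FALSE]
        planted_tr <- tr[tr$kind == "planted_pair", , drop = FALSE]
        decoy_tr <- tr[tr$kind %in% c("decoy_re", "decoy_are"), ,
                       drop = FALSE]
        protected <- data.frame(
          start = c(planted_tr$re_start, planted_tr$are_start,
                    decoy_tr$start),
          end = c(planted_tr$re_end, planted_tr$are_end, decoy_tr$end)
        )
      }
      seq_final <- scrub_stray_matches(
        seq_final, forbidden, protected, config$gc_content,
        seed = derive_seed(config$seed, i, 14L)
      )
    }
    genome[[i]] <- seq_final
  }
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth)) {
    truth <- data.frame(kind = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        re_start = numeric(0), re_end = numeric(0),
                        are_start = numeric(0), are_end = numeric(0),
                        spacer = numeric(0), orientation = character(0),
                        stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  # Peaks: cover the first ceiling(coverage * n) planted pairs in
  # deterministic span order, then background peaks over empty ground.
  planted <- truth[truth$kind == "planted_pair", , drop = FALSE]
  planted <- planted[order(planted$chrom, planted$start), , drop = FALSE]
  n_cover <- round(config$peak_coverage * nrow(planted))
  covered <- utils::head(planted, n_cover)
  peak_rows <- list()
  if (nrow(covered) > 0) {
    peak_rows[[1]] <- data.frame(
      chrom = covered$chrom,
      start = pmax(covered$start - config$peak_padding, 0),
      end = pmin(covered$end + config$peak_padding,
                 lens[covered$chrom]),
      stringsAsFactors = FALSE
    )
  }
  if (config$n_background_peaks > 0) {
    bg_alloc <- allocate_counts(lens, config$n_background_peaks)
    with_seed(derive_seed(config$seed, 1L, 12L), {
      for (i in seq_len(n_chrom)) {
        if (bg_alloc[[i]] == 0) next
        occ <- as.matrix(truth[truth$chrom == names(lens)[i],
                               c("start", "end"), drop = FALSE])
        placed <- sample_free_starts(
          lens[[i]], rep(config$background_peak_width, bg_alloc[[i]]),
          occ, guard = config$peak_padding + 10
        )
        peak_rows[[length(peak_rows) + 1]] <- data.frame(
          chrom = names(lens)[i], start = placed$starts,
          end = placed$starts + config$background_peak_width,
          stringsAsFactors = FALSE
        )
      }
    })
  }
  peaks <- if (length(peak_rows) > 0) do.call(rbind, peak_rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  peaks$center <- floor((peaks$start + peaks$end) / 2)
  peaks$name <- if (nrow(peaks) > 0) {
    sprintf("peak_%d", seq_len(nrow(peaks)))
  } else {
    character(0)
  }
  peaks$mark <- rep("H3K27ac", nrow(peaks))
  peaks$state <- rep("synthetic", nrow(peaks))
  rownames(peaks) <- NULL
  # TSS: placed at configured distances downstream/upstream of planted
  # pair spans (recycled over pairs), clamped to the chromosome.
  tss <- data.frame(feature_id = character(0), chrom = character(0),
                    position = numeric(0), strand = character(0),
                    source = character(0), stringsAsFactors = FALSE)
  if (config$n_tss > 0 && nrow(planted) > 0) {
    with_seed(derive_seed(config$seed, 1L, 13L), {
      anchor <- planted[rep(seq_len(nrow(planted)),
                            length.out = config$n_tss), , drop = FALSE]
      d <- draw_from_spec(config$tss_distance, config$n_tss)
      side <- ifelse(stats::runif(config$n_tss) < 0.5, -1, 1)
      pos <- ifelse(side < 0, anchor$start - d, anchor$end - 1 + d)
      pos <- pmin(pmax(pos, 0), lens[anchor$chrom] - 1)
      tss <- data.frame(
        feature_id = sprintf("gene_%d", seq_len(config$n_tss)),
        chrom = anchor$chrom, position = pos,
        strand = ifelse(side < 0, "-", "+"),
        source = "gene", stringsAsFactors = FALSE
      )
    })
    tss_truth <- data.frame(
      kind = "tss", chrom = tss$chrom, start = tss$position,
      end = tss$position + 1, re_start = NA_real_, re_end = NA_real_,
      are_start = NA_real_, are_end = NA_real_, spacer = NA_real_,
      orientation = NA_character_, stringsAsFactors = FALSE
    )
    truth <- rbind(truth, tss_truth)
  }
  structure(
    list(genome = as_genome(genome), truth = truth, peaks = peaks,
         tss = tss, config = config),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic world: %d chromosome(s) (%.0f bp), %d planted pair(s), %d peak(s), %d TSS\n",
    length(x$genome), sum(nchar(x$genome)),
    sum(x$truth$kind == "planted_pair"), nrow(x$peaks), nrow(x$tss)))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits exactly the formats the pipeline consumes: genome FASTA, peak BED,
#' TSS table, plus the truth TSV. Output is byte-identical for identical
#' config and seed.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    peaks = file.path(dir, "peaks.bed"),
    tss = file.path(dir, "tss.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_genome_fasta(world$genome, paths[["genome"]])
  write_tables(world$peaks, paths[["peaks"]], format = "bed")
  con <- file(paths[["tss"]], open = "wt")
  writeLines("# feature_id\tchrom\tposition\tstrand", con)
  if (nrow(world$tss) > 0) {
    utils::write.table(
      format(world$tss[c("feature_id", "chrom", "position", "strand")],
             scientific = FALSE, trim = TRUE),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  close(con)
  write_tables(world$truth, paths[["truth"]], format = "tsv")
  invisible(paths)
}
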