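# Full-analysis orchestration: scan -> pair -> null -> stats -> annotate ->
# associate -> export, writing every intermediate in the documented formats
# so each stage is independently reproducible.

#' Configure a full analysis run
#'
#' Holds every tunable constant of the analysis; defaults are the
#' reproduction settings (steric threshold 7 bp, enrichment window 2000 bp,
#' peak half-width 300 bp, gene association within 100 kb).
#'
#' @param genome_path FASTA genome.
#' @param motif_path motif configuration table (name<TAB>IUPAC pattern,
#'   must contain motifs named RE and ARE); NULL uses [default_motifs()].
#' @param peak_paths named character vector of peak BED paths; names encode
#'   "mark:state" (e.g. `c("H3K27ac:KP" = "kp.bed")`).
#' @param tss_paths named character vector of TSS table paths; names are the
#'   source tags ("gene", "mirna").
#' @param steric_threshold minimum spacer (exclusive) for simultaneous
#'   binding, bases.
#' @param window enrichment window, bases.
#' @param max_gene_dist closest-gene association cutoff, bases.
#' @param containment_mode "reported_range" or "center_window".
#' @param peak_half_width half-width for "center_window" mode, bases.
#' @param max_window nearest-pairing search window (Inf = unlimited).
#' @param strands strands to scan ("both" or "+").
#' @param tss_one_based TRUE when TSS tables use 1-based positions.
#' @param seed master seed for the null simulation.
#' @param out_dir output directory.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(genome_path, motif_path = NULL,
                            peak_paths = character(0),
                            tss_paths = character(0),
                            steric_threshold = 7, window = 2000,
                            max_gene_dist = 100000,
                            containment_mode = "reported_range",
                            peak_half_width = 300, max_window = Inf,
                            strands = "both", tss_one_based = FALSE,
                            seed = 1L, out_dir = "reare_out") {
  structure(
    list(genome_path = genome_path, motif_path = motif_path,
         peak_paths = peak_paths, tss_paths = tss_paths,
         steric_threshold = steric_threshold, window = window,
         max_gene_dist = max_gene_dist,
         containment_mode = containment_mode,
         peak_half_width = peak_half_width, max_window = max_window,
         strands = strands, tss_one_based = tss_one_based,
         seed = as.integer(seed), out_dir = out_dir),
    class = "analysis_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

write_kv <- function(kv, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# key\tvalue", con)
  writeLines(sprintf("%s\t%s", names(kv), vapply(kv, as.character,
                                                 character(1))), con)
  invisible(path)
}

#' Run the full RE-ARE analysis
#'
#' Scans the genome for RE and ARE motifs, pairs each RE with its nearest
#' ARE, simulates the matched randomized-genome null, compares spacer (and,
#' when TSS tables are given, TSS-distance) distributions, annotates peaks
#' with contained pairs and per-state percentages, derives unique/common
#' peak sets when exactly two states are given, assigns closest genes, and
#' exports pair sequences. All outputs land in `config$out_dir` together
#' with the resolved configuration and a run log; reruns with the same
#' config and seed are byte-identical.
#'
#' @param config an [analysis_config()].
#' @return the output directory path, invisibly; the full result list is
#'   attached as attribute `"results"`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  genome <- stage("genome_io", read_genome_fasta(config$genome_path))
  motifs <- stage("genome_io", {
    if (is.null(config$motif_path)) default_motifs()
    else read_motif_table(config$motif_path)
  })
  if (!all(c("RE", "ARE") %in% names(motifs))) {
    stop("stage 'genome_io' failed: motif table must define RE and ARE",
         call. = FALSE)
  }
  log_msg("rearescan %s | seed %d | steric > %g bp | window %g bp | gene cutoff %g bp",
          as.character(utils::packageVersion("rearescan")), config$seed,
          config$steric_threshold, config$window, config$max_gene_dist)

  scan <- stage("scan", scan_genome(motifs[c("RE", "ARE")], genome,
                                    strands = config$strands))
  write_tables(scan$hits, file.path(config$out_dir, "hits.bed"),
               format = "bed")
  write_tables(scan$counts, file.path(config$out_dir, "hit_counts.tsv"))
  log_msg("scan: %.0f RE, %.0f ARE hits", scan$totals[["RE"]],
          scan$totals[["ARE"]])

  re_hits <- scan$hits[scan$hits$motif == "RE", , drop = FALSE]
  are_hits <- scan$hits[scan$hits$motif == "ARE", , drop = FALSE]
  pairs <- stage("pair", pair_nearest(
    re_hits, are_hits, max_window = config$max_window,
    steric_threshold = config$steric_threshold
  ))
  write_tables(pairs, file.path(config$out_dir, "pairs.tsv"))
  steric <- flag_steric(pairs, config$steric_threshold)
  log_msg("pair: %d pairs (%d sterically feasible, %d infeasible)",
          nrow(pairs), steric$counts[["feasible"]],
          steric$counts[["infeasible"]])

  null_spec <- null_genome_spec(
    chrom_lengths = chrom_lengths(genome),
    n_re = nrow(re_hits), n_are = nrow(are_hits),
    re_length = motifs$RE$length, are_length = motifs$ARE$length,
    seed = config$seed
  )
  null_sim <- stage("nullsim", simulate_null_pairs(
    null_spec, max_window = config$max_window,
    steric_threshold = config$steric_threshold
  ))
  write_tables(null_sim$pairs, file.path(config$out_dir, "null_pairs.tsv"))
  log_msg("nullsim: %d null pairs", nrow(null_sim$pairs))

  comparison <- NULL
  if (nrow(pairs) > 0 && nrow(null_sim$pairs) > 0) {
    comparison <- stage("stats", compare_real_vs_null(
      pairs, null_sim$pairs, window = config$window
    ))
    write_comparison_report(comparison,
                            file.path(config$out_dir,
                                      "spacer_comparison.tsv"))
    log_msg("stats: window fraction %.4f vs %.4f (null), KS D = %.4g, p = %s",
            comparison$window_fraction_real,
            comparison$window_fraction_null, comparison$ks$d_stat,
            format_p_value(comparison$ks$p_value))
  }

  tss_all <- NULL
  tss_comparison <- NULL
  if (length(config$tss_paths) > 0) {
    tss_all <- stage("genome_io", do.call(rbind, lapply(
      seq_along(config$tss_paths), function(i) {
        src <- names(config$tss_paths)[i]
        if (is.null(src) || is.na(src) || !nzchar(src)) src <- "gene"
        read_tss_table(config$tss_paths[[i]], source = src,
                       one_based = config$tss_one_based)
      })))
    if (nrow(pairs) > 0 && nrow(null_sim$pairs) > 0 && nrow(tss_all) > 0) {
      tss_comparison <- stage("stats", {
        d_real <- distance_to_nearest(tss_all, pairs)
        d_null <- distance_to_nearest(tss_all, null_sim$pairs)
        compare_real_vs_null(d_real$distances, d_null$distances,
                             window = config$window)
      })
      write_comparison_report(
        tss_comparison,
        file.path(config$out_dir, "tss_distance_comparison.tsv")
      )
      log_msg("stats: TSS-distance KS D = %.4g, p = %s",
              tss_comparison$ks$d_stat,
              format_p_value(tss_comparison$ks$p_value))
    }
  }

  annotations <- list()
  percentages <- NULL
  set_report <- NULL
  if (length(config$peak_paths) > 0) {
    for (i in seq_along(config$peak_paths)) {
      tag <- names(config$peak_paths)[i]
      if (is.null(tag) || is.na(tag) || !nzchar(tag)) {
        tag <- sprintf("peaks_%d", i)
      }
      parts <- strsplit(tag, ":", fixed = TRUE)[[1]]
      peaks <- stage("annotate", read_bed(
        config$peak_paths[[i]], mark = parts[1],
        state = if (length(parts) > 1) parts[2] else "other"
      ))
      annotations[[tag]] <- stage("annotate", pairs_under_peaks(
        pairs, peaks, mode = config$containment_mode,
        half_width = config$peak_half_width,
        re_hits = re_hits, are_hits = are_hits
      ))
      write_tables(annotations[[tag]]$peaks,
                   file.path(config$out_dir,
                             sprintf("annotated_peaks_%s.tsv",
                                     gsub(":", "_", tag))))
    }
    percentages <- do.call(rbind, lapply(annotations, percentage_with_pairs))
    rownames(percentages) <- NULL
    write_tables(percentages, file.path(config$out_dir, "percentages.tsv"))
    log_msg("annotate: %d peak set(s); %s", length(annotations),
            paste(sprintf("%s %.2f%%", names(annotations),
                          percentages$percent_with_pairs),
                  collapse = ", "))
    if (length(annotations) == 2) {
      algebra <- stage("annotate", peak_set_algebra(annotations[[1]],
                                                    annotations[[2]]))
      set_report <- algebra
      write_kv(as.list(algebra$counts),
               file.path(config$out_dir, "set_algebra.tsv"))
      log_msg("annotate: unique/common %d/%d (A), %d/%d (B)",
              algebra$counts[["unique_a"]], algebra$counts[["common_a"]],
              algebra$counts[["unique_b"]], algebra$counts[["common_b"]])
    }
    if (!is.null(tss_all) && nrow(tss_all) > 0) {
      genes <- stage("associate", do.call(rbind, lapply(
        names(annotations), function(tag) {
          g <- associate_genes(annotations[[tag]], tss_all,
                               max_dist = config$max_gene_dist)
          if (nrow(g) > 0) cbind(peak_set = tag, g)
          else cbind(peak_set = character(0), g)
        })))
      write_tables(genes, file.path(config$out_dir, "gene_assignments.tsv"))
      log_msg("associate: %d gene assignment row(s)", nrow(genes))
    }
  }

  stage("export", export_pair_sequences(
    pairs, genome, flank = 0,
    path = file.path(config$out_dir, "pair_sequences.fasta")
  ))

  resolved <- config
  resolved$max_window <- if (is.finite(config$max_window))
    config$max_window else "unlimited"
  write_kv(
    lapply(unclass(resolved), function(v) paste(v, collapse = ",")),
    file.path(config$out_dir, "run_config.tsv")
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  results <- list(scan = scan, pairs = pairs, null = null_sim,
                  comparison = comparison, tss_comparison = tss_comparison,
                  annotations = annotations, percentages = percentages,
                  set_algebra = set_report)
  out <- config$out_dir
  attr(out, "results") <- results
  invisible(out)
}
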