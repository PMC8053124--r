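# Peak containment, percentages, set algebra, TSS distances and gene
# association.

mk_pair <- function(chrom, re_start, re_end, are_start, are_end) {
  pair_nearest(hit_row(chrom, re_start, re_end, motif = "RE"),
               hit_row(chrom, are_start, are_end, motif = "ARE"))
}

test_that("containment intervals follow both peak conventions", {
  pk <- peak_table("c1", 1000, 1400)
  expect_equal(containment_interval(pk, "reported_range"),
               data.frame(ci_start = 1000, ci_end = 1400))
  expect_equal(containment_interval(pk, "center_window", half_width = 300),
               data.frame(ci_start = 900, ci_end = 1500))
  tiny <- peak_table("c1", 5000, 5001)
  ci <- containment_interval(tiny, "center_window", half_width = 300)
  expect_equal(ci$ci_end - ci$ci_start, 600)
})

test_that("a pair is under a peak only when both motifs are fully inside", {
  pk <- peak_table("c1", 1000, 1400)
  inside <- mk_pair("c1", 1050, 1070, 1200, 1209)
  ann <- pairs_under_peaks(inside, pk)
  expect_equal(unname(ann$counts[["peaks_with_pairs"]]), 1)
  expect_equal(nrow(ann$assignments), 1)

  straddle <- mk_pair("c1", 990, 1010, 1200, 1209)
  ann2 <- pairs_under_peaks(straddle, pk)
  expect_equal(unname(ann2$counts[["peaks_with_pairs"]]), 0)

  # RE inside, ARE outside: no pair, but a single-motif peak when hit
  # tables are provided
  re_in <- hit_row("c1", 1050, 1070, motif = "RE")
  are_out <- hit_row("c1", 1500, 1509, motif = "ARE")
  pair_out <- pair_nearest(re_in, are_out)
  ann3 <- pairs_under_peaks(pair_out, pk, re_hits = re_in,
                            are_hits = are_out)
  expect_equal(unname(ann3$counts[["peaks_with_pairs"]]), 0)
  expect_equal(unname(ann3$counts[["single_motif_peaks"]]), 1)
  expect_true(ann3$peaks$single_motif_only[1])
})

test_that("a pair under two overlapping peaks is assigned to each", {
  pks <- peak_table("c1", c(1000, 1100), c(1400, 1500))
  pair <- mk_pair("c1", 1150, 1170, 1300, 1309)
  ann <- pairs_under_peaks(pair, pks)
  expect_equal(unname(ann$counts[["peaks_with_pairs"]]), 2)
  expect_equal(unname(ann$counts[["pairs_under_peaks"]]), 1)
  expect_equal(unname(ann$counts[["multiply_assigned_pairs"]]), 1)
})

test_that("percentages are computed per mark/state over all peaks", {
  pks <- peak_table("c1", seq(0, 11000, by = 1000),
                    seq(400, 11400, by = 1000))
  pairs <- do.call(rbind, lapply(c(0, 1000, 2000), function(s) {
    mk_pair("c1", s + 50, s + 70, s + 100, s + 109)
  }))
  ann <- pairs_under_peaks(pairs, pks)
  pct <- percentage_with_pairs(ann)
  expect_equal(pct$n_peaks, 12)
  expect_equal(pct$n_with_pairs, 3)
  expect_equal(pct$percent_with_pairs, 25)

  none <- pairs_under_peaks(mk_pair("c9", 0, 10, 20, 29), pks)
  expect_equal(percentage_with_pairs(none)$percent_with_pairs, 0)

  all_in <- pairs_under_peaks(
    do.call(rbind, lapply(seq(0, 11000, by = 1000), function(s) {
      mk_pair("c1", s + 50, s + 70, s + 100, s + 109)
    })), pks)
  expect_equal(percentage_with_pairs(all_in)$percent_with_pairs, 100)
})

test_that("cross-state peak identity is any-overlap on half-open intervals", {
  pair_for <- function(pk) mk_pair(pk$chrom, pk$start + 10, pk$start + 30,
                                   pk$start + 40, pk$start + 49)
  a <- peak_table("c1", 100, 200, state = "KP")
  b_overlap <- peak_table("c1", 150, 250, state = "DK")
  b_abut <- peak_table("c1", 200, 300, state = "DK")
  ann_a <- pairs_under_peaks(pair_for(a), a)
  alg <- peak_set_algebra(ann_a, pairs_under_peaks(pair_for(b_overlap),
                                                   b_overlap))
  expect_equal(unname(alg$counts[["common_a"]]), 1)
  expect_equal(unname(alg$counts[["unique_a"]]), 0)

  alg2 <- peak_set_algebra(ann_a, pairs_under_peaks(pair_for(b_abut),
                                                    b_abut))
  expect_equal(unname(alg2$counts[["common_a"]]), 0)
  expect_equal(unname(alg2$counts[["unique_a"]]), 1)

  b_other_chrom <- peak_table("c2", 100, 200, state = "DK")
  alg3 <- peak_set_algebra(ann_a,
                           pairs_under_peaks(pair_for(b_other_chrom),
                                             b_other_chrom))
  expect_equal(unname(alg3$counts[["unique_a"]]), 1)
  expect_equal(unname(alg3$counts[["unique_b"]]), 1)
})

test_that("unique + common partitions the RE-ARE-containing peaks", {
  set.seed(17)
  for (rep in 1:15) {
    n_a <- sample(3:12, 1); n_b <- sample(3:12, 1)
    mk_state <- function(n, state) {
      starts <- sort(sample(seq(0, 50000, by = 700), n))
      pks <- peak_table("c1", starts, starts + 500, state = state)
      prs <- do.call(rbind, lapply(starts, function(s) {
        mk_pair("c1", s + 50, s + 70, s + 100, s + 109)
      }))
      pairs_under_peaks(prs, pks)
    }
    alg <- peak_set_algebra(mk_state(n_a, "KP"), mk_state(n_b, "DK"))
    expect_equal(unname(alg$counts[["unique_a"]] + alg$counts[["common_a"]]),
                 unname(alg$counts[["n_a"]]))
    expect_equal(unname(alg$counts[["unique_b"]] + alg$counts[["common_b"]]),
                 unname(alg$counts[["n_b"]]))
  }
})

test_that("nearest distances are zero inside spans and gaps outside", {
  pair <- mk_pair("c1", 600, 620, 650, 699)  # span [600, 700)
  tss <- function(pos, chrom = "c1") {
    data.frame(feature_id = "g", chrom = chrom, position = pos,
               strand = "+", source = "gene", stringsAsFactors = FALSE)
  }
  expect_equal(distance_to_nearest(tss(500), pair)$distances, 100)
  expect_equal(distance_to_nearest(tss(650), pair)$distances, 0)

  two_targets <- rbind(mk_pair("c1", 600, 620, 650, 699),
                       mk_pair("c1", 900, 920, 950, 999))
  # gaps 101 (to base 699) and 100 (to base 900): the minimum wins
  expect_equal(distance_to_nearest(tss(800), two_targets)$distances, 100)

  unmatched <- distance_to_nearest(tss(5, chrom = "cX"), pair)
  expect_equal(unmatched$unmatched, 1)
  expect_length(unmatched$distances, 0)

  # symmetric direction: pair spans against TSS points
  d_rev <- distance_to_nearest(pair, tss(500))
  expect_equal(d_rev$distances, 100)
})

test_that("nearest distances agree with the brute-force minimizer", {
  set.seed(23)
  for (rep in 1:15) {
    n_t <- sample(1:50, 1)
    st <- floor(runif(n_t, 0, 20000))
    targets <- data.frame(chrom = sample(c("c1", "c2"), n_t, replace = TRUE),
                          span_start = st, span_end = st + sample(20:200, n_t,
                                                                  replace = TRUE))
    n_q <- sample(1:50, 1)
    queries <- data.frame(feature_id = paste0("g", 1:n_q),
                          chrom = sample(c("c1", "c2"), n_q, replace = TRUE),
                          position = floor(runif(n_q, 0, 20000)),
                          strand = "+", source = "gene")
    got <- distance_to_nearest(queries, targets)
    want <- oracle_point_to_span(queries$position, queries$chrom, targets)
    expect_equal(got$distances, want[got$query_idx])
    expect_equal(got$unmatched, which(is.na(want)))
  }
})

test_that("gene association honours the distance cutoff and duplicates rows", {
  pk <- peak_table("c1", 4000, 6001)  # center 5000
  pair1 <- mk_pair("c1", 4100, 4120, 4200, 4209)
  tss_at <- function(pos, id = "g1") {
    data.frame(feature_id = id, chrom = "c1", position = pos, strand = "+",
               source = "gene", stringsAsFactors = FALSE)
  }
  ann <- pairs_under_peaks(pair1, pk)
  inside <- associate_genes(ann, tss_at(104999), max_dist = 100000)
  expect_equal(inside$feature_id, "g1")
  expect_equal(inside$distance, 99999)
  expect_true(inside$assigned)

  outside <- associate_genes(ann, tss_at(105001), max_dist = 100000)
  expect_equal(outside$feature_id, "unassigned")
  expect_false(outside$assigned)

  # two contained pairs => the gene is listed twice
  two_pairs <- rbind(pair1, mk_pair("c1", 5000, 5020, 5100, 5109))
  ann2 <- pairs_under_peaks(two_pairs, pk)
  dup <- associate_genes(ann2, tss_at(10000), max_dist = 100000)
  expect_equal(nrow(dup), 2)
  expect_equal(dup$feature_id, c("g1", "g1"))
  expect_equal(length(unique(dup$pair_idx)), 2)

  single_row <- associate_genes(ann2, tss_at(10000), max_dist = 100000,
                                duplicate_per_pair = FALSE)
  expect_equal(nrow(single_row), 1)

  # signed distance: TSS upstream of the center is negative
  neg <- associate_genes(ann, tss_at(4000), max_dist = 100000)
  expect_equal(neg$distance, -1000)
})
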