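# Nearest-ARE pairing, spacer arithmetic, steric filtering and sequence
# export.

test_that("spacer is the signed inner gap and is symmetric", {
  re <- hit_row("c1", 100, 120, motif = "RE")
  expect_equal(as.numeric(spacer(re, hit_row("c1", 150, 159))), 30)
  expect_equal(attr(spacer(re, hit_row("c1", 150, 159)), "orientation"),
               "RE_upstream")

  ov <- spacer(re, hit_row("c1", 110, 119))
  expect_equal(as.numeric(ov), -10)
  expect_equal(attr(ov, "orientation"), "overlapping")

  up <- spacer(hit_row("c1", 200, 220, motif = "RE"), hit_row("c1", 100, 109))
  expect_equal(as.numeric(up), 91)
  expect_equal(attr(up, "orientation"), "ARE_upstream")

  expect_error(spacer(re, hit_row("c2", 150, 159)), "same chromosome")

  set.seed(3)
  for (i in 1:25) {
    a <- hit_row("c1", s <- floor(runif(1, 0, 500)), s + sample(5:30, 1))
    b <- hit_row("c1", s2 <- floor(runif(1, 0, 500)), s2 + sample(5:30, 1))
    expect_equal(as.numeric(spacer(a, b)), as.numeric(spacer(b, a)))
  }
})

test_that("each RE pairs with the ARE of minimal absolute spacer", {
  re <- hit_row("c1", 100, 120, motif = "RE")
  ares <- rbind(hit_row("c1", 10, 19, motif = "ARE"),
                hit_row("c1", 150, 159, motif = "ARE"))
  p <- pair_nearest(re, ares)
  expect_equal(nrow(p), 1)
  expect_equal(p$are_start, 150)
  expect_equal(p$spacer, 30)

  # many-to-one: two REs may share one ARE
  res2 <- rbind(hit_row("c1", 100, 120, motif = "RE"),
                hit_row("c1", 200, 220, motif = "RE"))
  one_are <- hit_row("c1", 150, 159, motif = "ARE")
  p2 <- pair_nearest(res2, one_are)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$are_start, c(150, 150))

  # equidistant left/right: documented tie rule picks the lower coordinate
  tie <- pair_nearest(hit_row("c1", 100, 120, motif = "RE"),
                      rbind(hit_row("c1", 60, 70, motif = "ARE"),
                            hit_row("c1", 150, 160, motif = "ARE")))
  expect_equal(tie$spacer, 30)
  expect_equal(tie$are_start, 60)

  # empty inputs and missing chromosomes are empty results, not errors
  expect_equal(nrow(pair_nearest(res2[0, ], one_are)), 0)
  expect_equal(nrow(pair_nearest(hit_row("c9", 0, 10), one_are)), 0)
})

test_that("pairing equals the all-pairs brute-force minimizer", {
  set.seed(202)
  for (rep in 1:20) {
    re <- random_hits(sample(1:60, 1), motif = "RE")
    n_are <- sample(1:120, 1)
    ch <- sample(c("chr1", "chr2"), n_are, replace = TRUE)
    st <- floor(runif(n_are, 0, 10000))
    are <- data.frame(chrom = ch, start = st, end = st + 9, strand = "+",
                      motif = "ARE", seq = NA, stringsAsFactors = FALSE)
    got <- pair_nearest(re, are)
    want <- oracle_pair(re, are)
    key <- function(d) do.call(order, d[c("re_start", "re_end")])
    got <- got[key(got), ]
    want <- want[key(want), ]
    expect_equal(got$spacer, want$spacer)
    expect_equal(got$are_start, want$are_start)
  }
})

test_that("max_window restricts pairs and one-to-one mode forbids ARE reuse", {
  res2 <- rbind(hit_row("c1", 100, 120, motif = "RE"),
                hit_row("c1", 300, 320, motif = "RE"))
  ares <- rbind(hit_row("c1", 130, 139, motif = "ARE"),
                hit_row("c1", 150, 159, motif = "ARE"))
  expect_equal(nrow(pair_nearest(res2, ares, max_window = 50)), 1)

  p11 <- pair_nearest(res2, ares, one_to_one = TRUE)
  expect_equal(nrow(p11), 2)
  expect_equal(anyDuplicated(p11$are_start), 0)
  expect_equal(sort(p11$are_start), c(130, 150))

  # more REs than AREs: the surplus RE stays unpaired
  res3 <- rbind(res2, hit_row("c1", 500, 520, motif = "RE"))
  p3 <- pair_nearest(res3, ares[1, ], one_to_one = TRUE)
  expect_equal(nrow(p3), 1)
})

test_that("steric feasibility is a strict > threshold rule", {
  mk <- function(sp) {
    pair_nearest(hit_row("c1", 100, 120, motif = "RE"),
                 hit_row("c1", 120 + sp, 129 + sp, motif = "ARE"))
  }
  expect_true(mk(8)$steric_ok)
  expect_false(mk(7)$steric_ok)

  pairs <- rbind(mk(8), mk(7), mk(-3))
  parts <- flag_steric(pairs, threshold = 7)
  expect_equal(unname(parts$counts), c(1, 2))
  expect_equal(parts$feasible$spacer, 8)
  expect_setequal(parts$infeasible$spacer, c(7, -3))
})

test_that("pair sequence export slices the genome with flanks and clipping", {
  set.seed(9)
  genome <- as_genome(c(c1 = random_dna(300, with_n = FALSE)))
  pairs <- pair_nearest(hit_row("c1", 100, 120, motif = "RE"),
                        hit_row("c1", 150, 159, motif = "ARE"))
  s0 <- export_pair_sequences(pairs, genome, flank = 0)
  expect_equal(nchar(unname(s0)), 59)
  expect_equal(unname(s0), substring(genome[["c1"]], 101, 159))

  s20 <- export_pair_sequences(pairs, genome, flank = 20)
  expect_equal(nchar(unname(s20)), 99)

  expect_warning(sclip <- export_pair_sequences(pairs, genome, flank = 200),
                 "clipped")
  expect_equal(nchar(unname(sclip)), 300)

  expect_error(export_pair_sequences(pairs, as_genome(c(other = "ACGT")),
                                     flank = 0),
               "unknown chromosome")
})
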