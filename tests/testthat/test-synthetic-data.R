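# Synthetic worlds: realized motifs, clean backgrounds, planted truth.

test_that("realized motif instances always match their motif", {
  exact <- compile_motif("M", "TGAC")
  expect_equal(realize_motif_instance(exact), "TGAC")

  ry <- compile_motif("RY", "RY")
  set.seed(1)
  draws <- replicate(30, realize_motif_instance(ry))
  expect_true(all(draws %in% c("AC", "AT", "GC", "GT")))

  expect_equal(realize_motif_instance(ry, seed = 5),
               realize_motif_instance(ry, seed = 5))
})

test_that("background generation honours GC content and exclusions", {
  expect_equal(generate_background(0), "")

  gc1 <- generate_background(500, gc_content = 0.999, seed = 2)
  expect_gt(mean(strsplit(gc1, "")[[1]] %in% c("G", "C")), 0.98)

  m <- compile_motif("M", "TGAC")
  clean <- generate_background(20000, forbidden_motifs = list(m), seed = 3)
  expect_equal(nrow(scan_sequence(m, clean)), 0)

  expect_error(generate_background(100,
                                   forbidden_motifs = list(
                                     compile_motif("NN", "NNNN"))),
               "every window")
})

test_that("planted pairs are recovered at their truth coordinates", {
  cfg <- synthetic_world_config(chrom_lengths = c(chr1 = 100000),
                                n_planted_pairs = 10,
                                spacer = list(kind = "fixed", k = 50),
                                n_decoy_re = 0, n_decoy_are = 0,
                                peak_coverage = 0.5, peak_padding = 100,
                                n_tss = 0, seed = 21)
  world <- plant_world(cfg)
  motifs <- default_motifs()
  sc <- scan_genome(motifs, world$genome, dedup = TRUE)
  pairs <- pair_nearest(sc$hits[sc$hits$motif == "RE", ],
                        sc$hits[sc$hits$motif == "ARE", ])
  planted <- world$truth[world$truth$kind == "planted_pair", ]
  expect_equal(nrow(pairs), 10)
  expect_equal(pairs$spacer, rep(50, 10))
  expect_setequal(pairs$re_start, planted$re_start)
  expect_setequal(pairs$are_start, planted$are_start)

  # exactly half the planted pairs lie under an emitted peak
  ann <- pairs_under_peaks(pairs, world$peaks)
  expect_equal(unname(ann$counts[["peaks_with_pairs"]]), 5)
  expect_equal(nrow(world$peaks), 5)
})

test_that("decoys and planted pairs account for every scanner hit", {
  cfg <- synthetic_world_config(chrom_lengths = c(chr1 = 80000,
                                                  chr2 = 40000),
                                n_planted_pairs = 6,
                                spacer = list(kind = "uniform",
                                              min = 20, max = 200),
                                n_decoy_re = 4, n_decoy_are = 9,
                                peak_coverage = 0, n_tss = 0, seed = 33)
  world <- plant_world(cfg)
  sc <- scan_genome(default_motifs(), world$genome, dedup = TRUE)
  truth <- world$truth
  re_truth <- c(truth$re_start[truth$kind == "planted_pair"],
                truth$start[truth$kind == "decoy_re"])
  are_truth <- c(truth$are_start[truth$kind == "planted_pair"],
                 truth$start[truth$kind == "decoy_are"])
  expect_setequal(sc$hits$start[sc$hits$motif == "RE"], re_truth)
  expect_setequal(sc$hits$start[sc$hits$motif == "ARE"], are_truth)
})

test_that("identical config and seed give byte-identical world files", {
  cfg <- synthetic_world_config(chrom_lengths = c(chr1 = 30000),
                                n_planted_pairs = 4, n_decoy_re = 2,
                                n_decoy_are = 3, n_tss = 5, seed = 9)
  d1 <- file.path(tempdir(), "world_a")
  d2 <- file.path(tempdir(), "world_b")
  p1 <- write_world(plant_world(cfg), d1)
  p2 <- write_world(plant_world(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }

  other <- synthetic_world_config(chrom_lengths = c(chr1 = 30000),
                                  n_planted_pairs = 4, n_decoy_re = 2,
                                  n_decoy_are = 3, n_tss = 5, seed = 10)
  expect_false(identical(plant_world(cfg)$truth, plant_world(other)$truth))
})

test_that("TSS are planted at their recorded distances from pair spans", {
  cfg <- synthetic_world_config(chrom_lengths = c(chr1 = 200000),
                                n_planted_pairs = 5,
                                spacer = list(kind = "fixed", k = 30),
                                n_decoy_re = 0, n_decoy_are = 0,
                                peak_coverage = 1, peak_padding = 50,
                                n_tss = 10,
                                tss_distance = list(kind = "fixed", k = 500),
                                seed = 14)
  world <- plant_world(cfg)
  planted <- world$truth[world$truth$kind == "planted_pair", ]
  planted$chrom <- as.character(planted$chrom)
  spans <- data.frame(chrom = planted$chrom, span_start = planted$start,
                      span_end = planted$end)
  d <- distance_to_nearest(world$tss, spans)
  expect_true(all(d$distances == 500))
})
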