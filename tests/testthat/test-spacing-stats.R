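# ECDFs, window fractions and the two-sample KS test.

test_that("ECDF is right-continuous with exact tie handling", {
  e <- spacing_ecdf(c(1, 2, 2, 4))
  expect_equal(e$support, c(1, 2, 4))
  expect_equal(e$fraction, c(0.25, 0.75, 1))
  expect_equal(e$fun(c(0, 1, 2, 3, 4, 5)), c(0, 0.25, 0.75, 0.75, 1, 1))

  single <- spacing_ecdf(7)
  expect_equal(single$fraction, 1)
  expect_equal(single$fun(6.9), 0)

  expect_error(spacing_ecdf(numeric(0)), "empty")
})

test_that("window fraction uses an inclusive boundary", {
  expect_equal(window_fraction(c(10, 500, 3000), 2000), 2 / 3)
  expect_equal(window_fraction(rep(2000, 5), 2000), 1)
  expect_equal(window_fraction(c(1, 2, 3), 0), 0)
  expect_error(window_fraction(numeric(0)), "empty")
  expect_error(window_fraction(c(1, 2), -1), "non-negative")
})

test_that("KS statistic hits its boundary cases exactly", {
  same <- ks_two_sample(c(1, 5, 9), c(1, 5, 9))
  expect_equal(same$d_stat, 0)
  expect_equal(same$p_value, 1)

  disjoint <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$d_stat, 1)

  mid <- ks_two_sample(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(mid$d_stat, 0.5)
  ref <- suppressWarnings(stats::ks.test(c(1, 2, 3, 4), c(3, 4, 5, 6),
                                         exact = FALSE))
  expect_equal(mid$p_value, unname(ref$p.value), tolerance = 1e-7)

  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

# Kolmogorov survival function in its theta-transformed form,
# Q(x) = 1 - sqrt(2*pi)/x * sum_k exp(-(2k-1)^2 pi^2 / (8 x^2)):
# mathematically identical to the alternating series but a different
# implementation, used as the converged reference for p-values.
kolmogorov_sf_theta <- function(x) {
  if (x < 1e-8) return(1)
  k <- seq_len(50)
  1 - sqrt(2 * pi) / x * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * x^2)))
}

test_that("D equals the brute-force sup over pooled points, with ties", {
  set.seed(31)
  for (rep in 1:25) {
    a <- sample(0:40, sample(2:60, 1), replace = TRUE)
    b <- sample(0:40, sample(2:60, 1), replace = TRUE)
    got <- ks_two_sample(a, b)
    expect_equal(got$d_stat, oracle_ks_d(a, b))
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(got$d_stat, unname(ref$statistic))
    # ks.test evaluates the same asymptotic distribution with a series
    # truncated at 1e-6 per term; agree with it at that granularity and
    # with the converged theta-form evaluation much tighter
    expect_lt(abs(got$p_value - unname(ref$p.value)), 5e-5)
    ne <- length(a) * length(b) / (length(a) + length(b))
    expect_equal(got$p_value, kolmogorov_sf_theta(sqrt(ne) * got$d_stat),
                 tolerance = 1e-9)
  }
})

test_that("permutation p-value is calibrated on exchangeable samples", {
  set.seed(4)
  a <- rnorm(20)
  b <- rnorm(20)
  p <- ks_two_sample(a, b, exact = TRUE, n_perm = 500, perm_seed = 2)
  expect_gt(p$p_value, 0.05)
  # strong shift is detected
  p2 <- ks_two_sample(a, b + 5, exact = TRUE, n_perm = 500, perm_seed = 2)
  expect_lt(p2$p_value, 0.01)
})

test_that("real-vs-null comparison reports fractions, KS and histograms", {
  set.seed(12)
  real <- abs(rnorm(400, 100, 10))
  null <- floor(runif(400, 0, 10000))
  cmpr <- compare_real_vs_null(real, null, window = 2000)
  expect_gt(cmpr$window_fraction_difference, 0.5)
  expect_lt(cmpr$ks$p_value, 1e-6)
  expect_equal(sum(cmpr$histogram$count_real), 400)
  expect_equal(sum(cmpr$histogram$count_null), 400)

  # same generator, same seed: D = 0, p = 1
  ident <- compare_real_vs_null(null, null)
  expect_equal(ident$ks$d_stat, 0)
  expect_equal(ident$window_fraction_difference, 0)

  # report writing is deterministic
  f1 <- tempfile(); f2 <- tempfile()
  write_comparison_report(cmpr, f1)
  write_comparison_report(cmpr, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[2], "^window_bp\t2000")
})

test_that("p-value display floors at the conventional 2.2e-16", {
  expect_equal(format_p_value(1e-20), "< 2.2e-16")
  expect_equal(format_p_value(0.05), "0.05")
})
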