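test_that("ld_pmf matches the closed-form low-order probabilities", {
  # hand-derived from the recursion: p0 = e^-m, p1 = m e^-m / 2,
  # p2 = e^-m (m/6 + m^2/8)
  expect_equal(ld_pmf(0, 3)$pmf, c(1, 0, 0, 0))
  expect_equal(ld_pmf(1, 0)$pmf, exp(-1), tolerance = 1e-12)
  d <- ld_pmf(1, 2)$pmf
  expect_equal(d[2], exp(-1) / 2, tolerance = 1e-9)
  expect_equal(d[3], exp(-1) * (1 / 6 + 1 / 8), tolerance = 1e-9)
  d2 <- ld_pmf(2, 2)$pmf
  expect_equal(d2[2], 2 * exp(-2) / 2, tolerance = 1e-9)
  expect_equal(d2[3], exp(-2) * (2 / 6 + 4 / 8), tolerance = 1e-9)
  expect_error(ld_pmf(-1, 10), "non-negative")
})

test_that("ld_pmf is a decreasing sub-probability beyond its mode", {
  for (m in c(0.5, 1, 2, 5)) {
    p <- ld_pmf(m, 200)$pmf
    expect_true(all(p >= 0 & p <= 1))
    expect_lte(sum(p), 1 + 1e-12)
    above <- seq(ceiling(m) + 1, 200)
    expect_true(all(diff(p[above + 1]) < 0))
  }
})

test_that("the P0 estimator inverts the zero-class fraction", {
  counts <- c(rep(0, 37), rep(1, 63))
  expect_equal(estimate_m_p0(counts), -log(0.37), tolerance = 1e-9)
  expect_equal(estimate_m_p0(rep(0, 10)), 0)
  expect_error(estimate_m_p0(c(1, 2, 3)), "P0 inapplicable")
})

test_that("the MLE recovers m from counts drawn from its own model", {
  m_hats <- vapply(1:10, function(s) {
    estimate_m_mle(sample_lc_direct(1.5, 500, seed = 10 + s),
                   compute_ci = FALSE)$m_hat
  }, numeric(1))
  expect_lt(abs(mean(m_hats) - 1.5) / 1.5, 0.05)
  est <- estimate_m_mle(sample_lc_direct(1.5, 500, seed = 11))
  expect_lt(est$ci_low, est$m_hat)
  expect_gt(est$ci_high, est$m_hat)
  # P0 and MLE agree on the same samples at moderate m
  for (m in c(0.5, 1, 2)) {
    cts <- sample_lc_direct(m, 400, seed = 20 + m)
    expect_lt(abs(estimate_m_mle(cts)$m_hat - estimate_m_p0(cts)) / m, 0.10)
  }
})

test_that("the MLE handles boundaries and bad input", {
  est0 <- estimate_m_mle(rep(0, 50))
  expect_equal(est0$m_hat, 0)
  expect_equal(est0$ci_low, 0)
  expect_true(est0$boundary)
  expect_gt(est0$ci_high, 0)
  expect_error(estimate_m_mle(5), "at least 2")
  expect_error(estimate_m_mle(c(0, 3, 20000), n_max = 10000,
                              tail_bin = FALSE),
               "truncation limit exceeded")
  # with tail binning (the default) the same counts are usable
  expect_gt(estimate_m_mle(c(0, 3, 20000), n_max = 10000)$m_hat, 0)
})

test_that("jackpot counts are tail-binned, not dropped", {
  cts <- c(rep(0, 60), rep(2, 30), rep(15000, 6))
  est_cap <- estimate_m_mle(cts, n_max = 1000, compute_ci = FALSE)
  est_big <- estimate_m_mle(cts, n_max = 20000, compute_ci = FALSE)
  expect_gt(est_cap$m_hat, 0)
  expect_lt(abs(est_cap$m_hat - est_big$m_hat) / est_big$m_hat, 0.25)
})

test_that("CFU processing applies the 10-500 reliable-count rule", {
  p <- plate_count_set(c(8, 52, 187, 540), dilution_factor = 1e6,
                       plated_volume_ml = 0.1)
  est <- cfu_from_plates(p)
  expect_equal(est$cells_per_ml, 1.195e9)
  expect_equal(est$n_reliable, 2L)
  # closed interval includes both bounds
  expect_equal(cfu_from_plates(plate_count_set(c(10, 500)))$cells_per_ml,
               255)
  expect_error(cfu_from_plates(plate_count_set(c(5, 600))),
               "no countable plates")
})

test_that("CFU is order-invariant and scales linearly with dilution", {
  cts <- c(40, 320, 77, 505, 9, 130)
  a <- cfu_from_plates(plate_count_set(cts, 100, 0.2))
  b <- cfu_from_plates(plate_count_set(rev(cts), 100, 0.2))
  expect_equal(a$cells_per_ml, b$cells_per_ml)
  d <- cfu_from_plates(plate_count_set(cts, 1000, 0.2))
  expect_equal(d$cells_per_ml, 10 * a$cells_per_ml)
})

test_that("rate conversion is m / (Nt * target size)", {
  expect_equal(mutation_rate_per_bp(1, 1e9, 1), 1e-9)
  expect_equal(mutation_rate_per_bp(0, 1e9, 1), 0)
  expect_equal(mutation_rate_per_bp(2, 1e9, 50), 4e-11)
  expect_error(mutation_rate_per_bp(1, -1, 1), "positive")
  expect_error(mutation_rate_per_bp(1, 1e9, 0), "positive")
})
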