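test_that("branching sampler matches its analytic anchors", {
  expect_true(all(sample_ld_counts(0, 100, seed = 1) == 0))
  cts <- sample_ld_counts(1, 1e5, seed = 2)
  expect_equal(mean(cts == 0), exp(-1), tolerance = 0.01)
  # one-mutant cultures need a single last-generation mutation:
  # P = (m/2) e^-m at m = 1 (up to the finite-population factor)
  expect_equal(mean(cts == 1), 0.5 * exp(-1), tolerance = 0.01)
  # jackpot property: heavy upper tail
  expect_gt(var(cts) / mean(cts), 10)
})

test_that("scenario presets carry the per-medium scaling coefficients", {
  m63 <- scaling_scenario("M63")
  maa <- scaling_scenario("MAA")
  lb <- scaling_scenario("LB")
  expect_equal(c(m63$r, maa$r, lb$r), c(-14.6, -10.1, -5.1))
  expect_equal(c(m63$alpha, maa$alpha, lb$alpha), c(-4.9, -4.8, -2.4))
  expect_equal(c(m63$log10_M0, maa$log10_M0, lb$log10_M0),
               c(-6.1, -4.3, -5.4))
  expect_length(m63$genome_sizes_mb, 10)
  expect_equal(m63$genome_sizes_mb[1], 4.65)
  expect_equal(min(m63$genome_sizes_mb), 3.62)
  expect_error(scaling_scenario("M63", alpha = 0), "inconsistent")
})

test_that("panels are deterministic in the seed", {
  a <- gen_strain_panel(scaling_scenario("LB", seed = 9))
  b <- gen_strain_panel(scaling_scenario("LB", seed = 9))
  c <- gen_strain_panel(scaling_scenario("LB", seed = 10))
  expect_identical(a, b)
  expect_false(identical(a$counts, c$counts))
})

test_that("zero-noise panels sit exactly on both scaling laws", {
  sc <- scaling_scenario("M63", noise_sd_log10M = 0, noise_sd_mu = 0,
                         seed = 3)
  obs <- gen_strain_panel(sc)$observations
  f1 <- fit_genome_scaling(obs, n_perm = 50)
  f2 <- fit_growth_mutation(obs, n_perm = 50)
  expect_equal(f1$r, -14.6, tolerance = 1e-9)
  expect_equal(f2$alpha, -4.9, tolerance = 1e-9)
  expect_equal(f2$log10_M0, -6.1, tolerance = 1e-9)
})

test_that("panel medium ordering reproduces the nutrition shift", {
  s <- 6
  m63 <- gen_strain_panel(scaling_scenario("M63", seed = s))$observations
  lb <- gen_strain_panel(scaling_scenario("LB", seed = s))$observations
  sh <- media_shift_test(m63$mutation_rate, lb$mutation_rate)
  expect_lt(sh$p_value, 0.05)
})

test_that("the estimation bridge recovers true values per strain", {
  panel <- gen_strain_panel(scaling_scenario("LB", seed = 2))
  est <- analyze_strain_panel(panel)
  truth <- panel$observations
  expect_equal(est$strain_id, truth$strain_id)
  # per-strain agreement within assay noise
  expect_lt(max(abs(log10(est$mutation_rate) -
                      log10(truth$mutation_rate))), 0.25)
  expect_lt(max(abs(est$growth_rate - truth$growth_rate) /
                  truth$growth_rate), 0.15)
})

test_that("expression generator seeds and column means behave", {
  a <- gen_expression_table(seed = 3)
  b <- gen_expression_table(seed = 3)
  expect_identical(a, b)
  expect_gt(sd(colMeans(a$expression)), 0.05)  # offsets differ before norm
  nx <- normalize_expression(a$expression)
  expect_lt(sd(colMeans(nx)), 1e-12)
  expect_error(gen_expression_table(planted = c(g = 1.2)), "\\[-1, 1\\]")
})
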