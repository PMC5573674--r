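test_that("both fits recover exact coefficients on collinear input", {
  obs <- collinear_obs(r = -14.6, b = 2.5, alpha = -4.9, log10_M0 = -6.1)
  gfit <- fit_genome_scaling(obs, n_perm = 100)
  expect_equal(gfit$r, -14.6, tolerance = 1e-9)
  expect_equal(gfit$b, 2.5, tolerance = 1e-9)
  expect_equal(gfit$r2, 1, tolerance = 1e-9)
  expect_equal(gfit$spearman_rho, -1)
  mfit <- fit_growth_mutation(obs, n_perm = 100)
  expect_equal(mfit$alpha, -4.9, tolerance = 1e-9)
  expect_equal(mfit$log10_M0, -6.1, tolerance = 1e-9)
  expect_equal(mfit$M0, 10^-6.1, tolerance = 1e-9)
})

test_that("fit preconditions and degenerate cases are handled", {
  obs <- collinear_obs()
  expect_error(fit_genome_scaling(obs[1:2, ]), "insufficient")
  mixed <- obs
  mixed$medium[1] <- "LB"
  expect_error(fit_genome_scaling(mixed), "mix media")
  const <- obs
  const$mutation_rate <- 1e-8
  g <- fit_genome_scaling(const, n_perm = 100)
  expect_equal(g$r, 0, tolerance = 1e-12)
  expect_true(g$rho_flagged)
  expect_equal(g$spearman_rho, 0)
  constmu <- obs
  constmu$growth_rate <- 0.5
  expect_error(fit_growth_mutation(constmu), "degenerate predictor")
})

test_that("slope is equivariant under rate rescaling", {
  obs <- collinear_obs()
  obs$mutation_rate <- obs$mutation_rate * (1 + 0.05 * seq_len(nrow(obs)))
  f1 <- fit_genome_scaling(obs, n_perm = 100)
  f2 <- fit_growth_mutation(obs, n_perm = 100)
  scaled <- obs
  scaled$mutation_rate <- scaled$mutation_rate * 1e3
  g1 <- fit_genome_scaling(scaled, n_perm = 100)
  g2 <- fit_growth_mutation(scaled, n_perm = 100)
  expect_equal(g1$r, f1$r, tolerance = 1e-9)
  expect_equal(g1$b, f1$b + 3, tolerance = 1e-9)
  expect_equal(g2$alpha, f2$alpha, tolerance = 1e-9)
  expect_equal(g2$log10_M0, f2$log10_M0 + 3, tolerance = 1e-9)
})

test_that("spearman rho uses mid-ranks and flags zero variance", {
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 2, 3)), sqrt(3) / 2,
               tolerance = 1e-9)
  expect_warning(r <- spearman_rho(1:4, rep(2, 4)), "zero rank variance")
  expect_true(is.na(r))
  # invariance under strictly monotone transforms
  x <- c(0.3, 2.5, 1.1, 4.8, 0.9, 3.3)
  y <- c(9, 2, 7, 1, 5, 4)
  expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
  expect_equal(spearman_rho(x, y^3), spearman_rho(x, y))
  # cross-check against stats::cor's spearman with ties
  xt <- c(1, 2, 2, 3, 5, 5, 7)
  yt <- c(2, 1, 4, 4, 6, 8, 8)
  expect_equal(spearman_rho(xt, yt), cor(xt, yt, method = "spearman"),
               tolerance = 1e-12)
})

test_that("pearson r matches cor and flags zero variance", {
  expect_equal(pearson_r(1:4, c(6, 4, 3, 1)), cor(1:4, c(6, 4, 3, 1)))
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1, tolerance = 1e-12)
  expect_warning(r <- pearson_r(1:4, rep(1, 4)), "zero variance")
  expect_true(is.na(r))
})

test_that("exact permutation p-values match hand enumeration", {
  # identity on n=3: only the identity permutation attains rho = 1
  expect_equal(permutation_pvalue(1:3, 1:3, "spearman",
                                  alternative = "greater"), 1 / 6)
  # perfect anticorrelation on n=5, alternative less: 1 of 120
  expect_equal(permutation_pvalue(1:5, 5:1, "spearman",
                                  alternative = "less"), 1 / 120)
  expect_equal(permutation_pvalue(1:5, 5:1, "pearson",
                                  alternative = "less"), 1 / 120)
  # two-sided identity on n=3: |rho| = 1 at identity and reversal
  expect_equal(permutation_pvalue(1:3, 1:3, "spearman",
                                  alternative = "two-sided"), 2 / 6)
})

test_that("Monte-Carlo permutation p-values are seeded and bounded", {
  x <- rnorm(12)
  y <- rnorm(12)
  p1 <- permutation_pvalue(x, y, "pearson", n_perm = 500, seed = 3)
  p2 <- permutation_pvalue(x, y, "pearson", n_perm = 500, seed = 3)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
  # add-one correction floors the p-value
  xs <- 1:20
  expect_equal(permutation_pvalue(xs, xs, "spearman", n_perm = 199,
                                  seed = 1, alternative = "greater"),
               1 / 200)
})

test_that("media shift test detects one-sided paired log-rate shifts", {
  poor <- 10^(-7 + seq(0.3, 1.2, 0.1))
  rich <- 10^(-7.8 + seq(0.05, 0.5, 0.05))
  sh <- media_shift_test(poor, rich)
  expect_equal(sh$p_value, 2^-10, tolerance = 1e-12)
  expect_gt(sh$direction, 0)
  tied <- media_shift_test(poor, poor)
  expect_equal(tied$p_value, 1)
  expect_true(tied$flagged)
  expect_error(media_shift_test(poor[1:3], rich[1:3]), ">= 5")
})
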