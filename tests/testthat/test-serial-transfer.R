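test_that("well selection enforces the window and geometric tie-break", {
  # candidates 0.05, 0.02, 0.005; nearest to sqrt(0.001*0.05) = 0.00707 in
  # log OD is 0.005
  ods <- c(0.5, 0.2, 0.05, 0.02, 0.005, 8e-4, 1e-4, 1e-5)
  expect_equal(select_transfer_well(ods), 5L)
  expect_equal(select_transfer_well(c(0.3, 0.02, 1e-4)), 2L)
  expect_error(select_transfer_well(c(0.5, 0.3, 0.2)), "protocol failure")
  expect_error(select_transfer_well(rep(1e-5, 8)), "protocol failure")
})

test_that("the default deterministic protocol yields 8 generations a day", {
  tr <- run_serial_transfer()
  expect_equal(nrow(tr), 50)
  expect_equal(tr$generations_today, rep(8, 50), tolerance = 1e-12)
  expect_equal(tr$cumulative_generations[50], 400, tolerance = 1e-12)
  # steady state: with adaptation disabled every day has identical gain
  expect_equal(length(unique(round(tr$generations_today, 9))), 1L)
  # zero days: empty trajectory
  tr0 <- run_serial_transfer(transfer_protocol(n_days = 0))
  expect_equal(nrow(tr0), 0)
})

test_that("generation accounting telescopes over the trajectory", {
  proto <- transfer_protocol(od_noise_sd = 0.05)
  tr <- run_serial_transfer(proto, adaptation_model(), seed = 11)
  lhs <- tr$cumulative_generations[nrow(tr)]
  od_prev <- c(proto$od_init, tr$od[-nrow(tr)])
  rhs <- sum(log2(tr$od * tr$selected_dilution / od_prev))
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("every trajectory point sits exactly on the coupled rate law", {
  ad <- adaptation_model(mu_max = 8 * log(2) / 24 * 1.4125)
  tr <- run_serial_transfer(transfer_protocol(), ad)
  expect_equal(log10(tr$M), ad$log10_M0 + ad$alpha * tr$mu,
               tolerance = 1e-12)
  # adaptation raises mu monotonically and lowers M accordingly
  expect_true(all(diff(tr$mu) >= 0))
  expect_gt(attr(tr, "mu_fold_change"), 1.25)
  d_mu <- tr$mu[nrow(tr)] - ad$mu_start
  expect_equal(attr(tr, "log10_M_change"), ad$alpha * d_mu,
               tolerance = 1e-12)
})

test_that("day-level failures carry the day index", {
  # carrying capacity below the window ceiling is rejected at construction
  expect_error(transfer_protocol(carrying_capacity = 0.01))
  # a growth model that saturates every well fails on day 1
  sat <- function(od_start, mu, protocol) rep(0.4, length(od_start))
  st <- list(day = 0L, od_at_selection = 0.01, cumulative_generations = 0)
  expect_error(simulate_transfer_day(st, transfer_protocol(), 0.2,
                                     regrowth = sat),
               "protocol failure")
})

test_that("seeded stochastic trajectories are reproducible", {
  proto <- transfer_protocol(od_noise_sd = 0.1)
  a <- run_serial_transfer(proto, seed = 7)
  b <- run_serial_transfer(proto, seed = 7)
  c <- run_serial_transfer(proto, seed = 8)
  expect_identical(a$od, b$od)
  expect_false(identical(a$od, c$od))
})
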