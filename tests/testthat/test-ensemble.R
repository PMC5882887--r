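# Mean-square decay fitting and the H-infinity energy ratio.

test_that("exact geometric series is recovered to high precision", {
  k <- 0:40
  fit <- ensemble_mean_square(3 * 0.8^k)
  expect_equal(fit$mu, 0.8, tolerance = 1e-8)
  expect_equal(fit$alpha, 3, tolerance = 1e-8)
  expect_equal(fit$verdict, "stable")
})

test_that("constant series yields mu = 1 and no stability verdict", {
  fit <- ensemble_mean_square(rep(2, 30))
  expect_equal(fit$mu, 1, tolerance = 1e-10)
  expect_true(fit$verdict != "stable")
})

test_that("all-zero ensemble is inconclusive with undefined decay", {
  fit <- ensemble_mean_square(numeric(20))
  expect_equal(fit$verdict, "inconclusive")
  expect_true(isTRUE(fit$mu_undefined))
  expect_true(is.na(fit$mu))
})

test_that("noise-free AR(1) ensemble gives the squared decay 0.25", {
  m <- scalar_toy(a = 0.5, rho = 0L)
  trajs <- lapply(1:4, function(r) {
    simulate_grn(m, zero_gains(1), const_schedule(), 40, seed = r,
                 noise = "off", history = list(x = matrix(1), y = matrix(0)))
  })
  fit <- ensemble_mean_square(trajs, burn_in = 1)
  expect_equal(fit$mu, 0.25, tolerance = 1e-8)
})

test_that("energy ratio is zero for zero output and errors on zero input", {
  # L_x = L_y = 0: disturbances never enter, output stays zero
  m <- scalar_toy()
  tr0 <- lapply(1:2, function(r) {
    simulate_grn(m, zero_gains(1), const_schedule(), 30, seed = r,
                 noise = "off",
                 disturbance = list(vx = function(k) exp(-0.1 * k),
                                    vy = NULL))
  })
  r <- hinf_ratio(tr0)
  expect_equal(r$ratio, 0)
  expect_gt(r$energy_in, 0)

  trz <- lapply(1:2, function(r) {
    simulate_grn(m, zero_gains(1), const_schedule(), 30, seed = r,
                 noise = "off")
  })
  expect_error(hinf_ratio(trz), "zero")
})

test_that("pass-through construction has energy ratio one", {
  # fabricate a trajectory whose xerr equals the disturbance exactly
  K <- 25
  v <- matrix(sin(1 + (0:(K - 1))) * exp(-0.2 * (0:(K - 1))), 1)
  fake <- structure(list(
    K = K, n = 1, l = 1,
    x = matrix(0, 1, K + 1), y = matrix(0, 1, K + 1),
    xerr = cbind(v, 0), yerr = matrix(0, 1, K + 1),
    vx = v, vy = matrix(0, 1, K),
    history_x = matrix(0, 1, 1), history_y = matrix(0, 1, 1)),
    class = "grn_trajectory")
  r <- hinf_ratio(list(fake))
  expect_equal(r$ratio, 1, tolerance = 1e-12)
})

test_that("ensembles must share a horizon and have two members", {
  m <- scalar_toy()
  t1 <- simulate_grn(m, zero_gains(1), const_schedule(), 10, seed = 1)
  t2 <- simulate_grn(m, zero_gains(1), const_schedule(), 12, seed = 2)
  expect_error(ensemble_mean_square(list(t1)), "at least 2")
  expect_error(ensemble_mean_square(list(t1, t2)), "share a horizon")
})
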