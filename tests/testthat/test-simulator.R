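# Forward simulation: equilibria, closed forms, the defining error-dynamics
# identity, reproducibility, dropout channel, truncation convergence.

test_that("the origin is an equilibrium of network and estimator", {
  m <- scalar_toy()
  tr <- simulate_grn(m, zero_gains(1), const_schedule(), 30, seed = 1,
                     noise = "off")
  expect_true(all(tr$x == 0))
  expect_true(all(tr$y == 0))
  expect_true(all(tr$xhat == 0))
  expect_true(all(tr$xerr_direct == 0))
})

test_that("decoupled scalar recursion reproduces (-a)^k", {
  m <- scalar_toy(a = 0.5, rho = 0L)
  tr <- simulate_grn(m, zero_gains(1), const_schedule(), 20, seed = 1,
                     noise = "off",
                     history = list(x = matrix(1), y = matrix(0)))
  expect_equal(drop(tr$x), (-0.5)^(0:20), tolerance = 1e-14)
})

test_that("certain measurements pass through when alpha0 = 1", {
  m <- toy_model(3)
  m2 <- grn_model(A = m$A, B = m$B, C = m$C, D = m$D, E = m$E, F = m$F,
                  H = m$H, L_x = m$L_x, L_y = m$L_y, M = m$M, N = m$N,
                  rho1 = m$rho1, rho2 = m$rho2,
                  delta_m = m$delta_m, delta_M = m$delta_M,
                  tau_m = m$tau_m, tau_M = m$tau_M,
                  mu_kernel = m$mu_kernel, xi_kernel = m$xi_kernel,
                  alpha0 = 1, beta0 = 1, hill = 2, sigma = m$sigma)
  tr <- simulate_grn(m2, zero_gains(2), grn_schedule(2L, 2L), 40,
                     seed = 5, history = "random")
  expect_true(all(tr$alpha == 1))
  for (k in 0:(tr$K - 1)) {
    expect_equal(tr$Zx_tilde[, k + 1], drop(m2$M %*% tr$x[, k + 1]),
                 tolerance = 1e-14)
  }
})

test_that("direct error recursion equals subtraction across seeded runs", {
  fx <- grn_example("4.1a")
  for (s in 1:8) {
    tr <- simulate_grn(fx$model, fx$gains, fx$schedule, 60, seed = s,
                       disturbance = fx$disturbance,
                       uncertainty_mode = "paper-trig",
                       history = "random")
    scale <- max(abs(tr$xerr), abs(tr$yerr), 1)
    expect_lte(max(abs(tr$xerr - tr$xerr_direct)) / scale, 1e-10)
    expect_lte(max(abs(tr$yerr - tr$yerr_direct)) / scale, 1e-10)
  }
})

test_that("simulation is bitwise reproducible per seed", {
  fx <- grn_example("4.1b")
  a <- simulate_grn(fx$model, fx$gains, fx$schedule, 40, seed = 9,
                    uncertainty_mode = "random-contraction",
                    history = "random")
  b <- simulate_grn(fx$model, fx$gains, fx$schedule, 40, seed = 9,
                    uncertainty_mode = "random-contraction",
                    history = "random")
  expect_identical(a$x, b$x)
  expect_identical(a$yerr, b$yerr)
  expect_identical(a$alpha, b$alpha)
})

test_that("RNG streams are partitioned per role", {
  fx <- grn_example("4.1b")
  on_ <- simulate_grn(fx$model, fx$gains, fx$schedule, 40, seed = 9,
                      noise = "on", history = "random")
  off <- simulate_grn(fx$model, fx$gains, fx$schedule, 40, seed = 9,
                      noise = "off", history = "random")
  # toggling the noise source must not shift the dropout draws
  expect_identical(on_$alpha, off$alpha)
  expect_identical(on_$beta, off$beta)
})

test_that("dropout channel matches its Bernoulli mean", {
  for (p in c(0.5, 0.9)) {
    draws <- grnest:::.draw_bernoulli(1e5, p, seed = 20 + round(10 * p))
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lte(abs(mean(draws) - p), 3 * se)
  }
})

test_that("delay schedules are validated against the bounds", {
  m <- toy_model(2)
  g <- zero_gains(2)
  expect_error(
    simulate_grn(m, g, grn_schedule(10L, 2L), 10, seed = 1),
    "violates the bounds")
  expect_error(
    simulate_grn(m, g, grn_schedule(function(k) 1.5, 2L), 10, seed = 1),
    "integer-valued")
  # trigonometric schedules evaluate to integers despite floating noise
  fx <- grn_example("4.1a")
  tr <- simulate_grn(fx$model, fx$gains, fx$schedule, 12, seed = 1)
  expect_true(all(tr$delta %in% c(1L, 3L, 5L)))
  expect_true(all(tr$tau %in% c(1L, 3L, 5L)))
})

test_that("halving the truncation tolerance barely moves trajectories", {
  fx <- grn_example("4.1a")
  for (rt in c(1e-6, 1e-8)) {
    a <- simulate_grn(fx$model, fx$gains, fx$schedule, 40, seed = 4,
                      history = "random", rel_tol = rt)
    b <- simulate_grn(fx$model, fx$gains, fx$schedule, 40, seed = 4,
                      history = "random", rel_tol = rt / 2)
    sup <- max(abs(a$x), abs(a$y))
    expect_lte(max(abs(a$x - b$x), abs(a$y - b$y)), 10 * rt * sup)
  }
})

test_that("series square bound holds on random PSD instances", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(1:5, 1)
    m <- sample(1:8, 1)
    S <- matrix(rnorm(n * n), n, n)
    M <- crossprod(S)
    a <- runif(m)
    X <- matrix(rnorm(n * m), n, m)
    r <- series_square_bound(M, a, X)
    expect_gte(r$slack, -1e-10 * max(1, abs(r$rhs)))
  }
})

test_that("trajectory export has the documented layout", {
  m <- toy_model(4)
  tr <- simulate_grn(m, zero_gains(2), grn_schedule(2L, 2L), 10, seed = 1,
                     history = "random")
  tab <- trajectory_table(tr)
  expect_equal(nrow(tab), 11)
  expect_equal(names(tab)[1:3], c("k", "x.1", "x.2"))
  expect_equal(tab$x.1, tr$x[1, ])
  expect_true(is.na(tab$alpha[11]))
})

test_that("horizon must be positive", {
  m <- scalar_toy()
  expect_error(simulate_grn(m, zero_gains(1), const_schedule(), 0),
               "at least 1")
})
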