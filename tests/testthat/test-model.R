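# Hill regulation, sector machinery, uncertainty generator, model
# validation.

test_that("Hill activation matches its closed form and is monotone", {
  expect_equal(hill_activation(0, 2), 0)
  expect_equal(hill_activation(1, 2), 0.5)
  expect_equal(hill_activation(2, 2), 0.8)
  expect_equal(hill_activation(3, 1), 0.75)

  set.seed(41)
  s <- sort(runif(200, 0, 10))
  v <- hill_activation(s, 2)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v < 1))

  expect_error(hill_activation(-0.1, 2), "non-negative")
  expect_error(hill_activation(1, -1), "positive")
})

test_that("maximal Hill slope oracle: brute force agrees with calculus", {
  # derivative of s^2/(1+s^2) is 2s/(1+s^2)^2, maximized at s = 1/sqrt(3)
  s <- seq(0, 5, length.out = 20001)
  slope_grid <- max(2 * s / (1 + s^2)^2)
  expect_equal(slope_grid, 3 * sqrt(3) / 8, tolerance = 1e-6)
})

test_that("sector sampling certifies the Hill sector and finds violations", {
  g2 <- function(s) hill_activation(s, 2)
  grid <- seq(0, 5, length.out = 120)

  # identity activation sits exactly on the N2 = I boundary
  r_id <- verify_sector(function(s) s, c(0, 1), grid)
  expect_true(r_id$holds)
  expect_lte(r_id$max_violation, 1e-9)

  # max slope 3*sqrt(3)/8 < 0.65: the [0, 0.65] sector holds
  r_ok <- verify_sector(g2, default_sector2(), grid)
  expect_true(r_ok$holds)

  # slope 0.3 is exceeded near the max-slope point
  r_bad <- verify_sector(g2, c(0, 0.3), grid)
  expect_false(r_bad$holds)
  expect_gt(r_bad$max_violation, 0)
  # worst pair straddles the max-slope argument 1/sqrt(3)
  expect_true(min(r_bad$argmax) < 1 / sqrt(3) &&
                max(r_bad$argmax) > 1 / sqrt(3) * 0.5)

  expect_error(verify_sector(g2, c(0, 1), numeric(0)), "non-empty")
})

test_that("sector bounds require a sign-definite width and canonicalize", {
  expect_error(sector_bounds(diag(2), diag(2)), "sign-definite")
  sw <- sector_bounds(N1 = matrix(0, 2, 2), N2 = diag(0.65, 2))
  expect_true(sw$swapped)
  expect_equal(sw$N1, diag(0.65, 2))
  # Ntilde quantities are swap-invariant
  ref <- sector_bounds(N1 = diag(0.65, 2), N2 = matrix(0, 2, 2))
  expect_equal(sw$Ntilde1, ref$Ntilde1)
  expect_equal(sw$Ntilde2, ref$Ntilde2)
  expect_equal(ref$Ntilde2, diag(-0.325, 2))
})

test_that("uncertainty draws respect the contraction bound in every mode", {
  unc <- uncertainty_structure(R = diag(c(0.1, 0.3)), W1 = diag(0.1, 2))

  off <- sample_uncertainty(unc, 5, mode = "off")
  expect_true(all(vapply(off[1:6], function(m) all(m == 0), logical(1))))

  z <- sample_uncertainty(uncertainty_structure(R = matrix(0, 2, 2),
                                                W1 = diag(2)),
                          3, mode = "paper-trig")
  expect_true(all(z$DeltaA == 0))

  # k = 0 trigonometric contraction: diag(sin 0, cos 0) = diag(0, 1)
  tr0 <- sample_uncertainty(unc, 0, mode = "paper-trig")
  expect_equal(tr0$Nk, diag(c(0, 1)))
  expect_equal(tr0$DeltaA, diag(c(0.1, 0.3)) %*% diag(c(0, 1)) %*%
                 diag(0.1, 2))

  for (k in 0:20) {
    for (md in c("paper-trig", "random-contraction")) {
      d <- sample_uncertainty(unc, k, mode = md, seed = 7)
      expect_lte(max(svd(d$Nk)$d), 1 + 1e-12)
    }
  }
  expect_error(sample_uncertainty(unc, 1, mode = "random-contraction"),
               "seed")
})

test_that("noise intensity enforces the quadratic bound", {
  H <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  expect_equal(noise_intensity(c(1, 2), matrix(0, 2, 2), H), c(0, 0))

  eh <- eigen(H, symmetric = TRUE)
  Hroot <- eh$vectors %*% (sqrt(eh$values) * t(eh$vectors))
  expect_equal(crossprod(Hroot), H, tolerance = 1e-12)
  expect_equal(noise_intensity(c(1, -1), Hroot, H),
               drop(Hroot %*% c(1, -1)))

  expect_error(noise_intensity(c(1, 1), 2 * Hroot, H), "bound")

  # random factor with shrunk spectrum: bound holds on random states
  set.seed(11)
  S <- matrix(rnorm(4), 2, 2)
  S <- S / (2 * max(svd(S)$d)) * sqrt(min(eigen(H)$values))
  for (i in 1:100) {
    x <- rnorm(2)
    v <- noise_intensity(x, S, H)
    expect_lte(sum(v^2), drop(t(x) %*% H %*% x) + 1e-12)
  }
})

test_that("model constructor validates its invariants", {
  ok <- scalar_toy()
  expect_s3_class(ok, "grn_model")
  expect_error(scalar_toy(a = -0.1), "strictly positive")
  base <- function(...) {
    args <- modifyList(list(
      A = matrix(0.5), B = matrix(0), C = matrix(0.5), D = matrix(1),
      E = matrix(0), F = matrix(0), H = matrix(1),
      L_x = matrix(0), L_y = matrix(0), M = matrix(1), N = matrix(1)),
      list(...))
    do.call(grn_model, args)
  }
  expect_error(base(H = matrix(-1)), "positive definite")
  expect_error(base(delta_m = 3, delta_M = 1), "bounds")
  expect_error(base(alpha0 = 0), "0, 1")
  expect_error(base(alpha0 = 1.2), "0, 1")
  expect_error(base(sigma = matrix(2)), "intensity bound")
})
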