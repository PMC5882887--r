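# Packaged parameter sets and the random stable model generator.

test_that("the first example's printed matrices are stored verbatim", {
  a <- grn_example("4.1a")
  expect_equal(a$model$A, diag(c(0.1, 0.2)))
  expect_equal(a$model$B, diag(c(0.08, 0.2)))
  expect_equal(a$model$E, diag(c(0.36, 0.1)))
  expect_equal(a$model$F, diag(0.4, 2))
  expect_equal(a$model$uncertainty$R, diag(0.2, 2))
  expect_equal(a$model$uncertainty$W1, diag(0.3, 2))
  expect_equal(a$model$rho1, 1L)
  expect_equal(a$model$rho2, 1L)
  expect_equal(a$model$mu_kernel$rate, 2)
  expect_equal(a$model$extras$d2, diag(c(0.28, 0.135)))

  b <- grn_example("4.1b")
  expect_equal(b$model$A, diag(0.1, 2))
  expect_equal(b$model$B, diag(c(-0.1, 0.2)))
  expect_equal(b$model$C, diag(0.2, 2))
  expect_equal(b$model$M, diag(c(0.6, 0.1)))
  expect_equal(b$model$N, matrix(c(0.4, 0.3, 0, 0.5), 2, 2))
  expect_equal(b$model$alpha0, 0.001)
  expect_equal(b$model$beta0, 0.003)
  expect_equal(b$model$uncertainty$R, diag(c(0.1, 0.3)))
  expect_equal(b$model$mu_kernel$rate, 1)
  # the printed d1 expressions evaluated: 0.2(cos(pi/2)-2), 0.1(sin(pi/2)-1)
  expect_equal(b$model$extras$d1, diag(c(-0.4, 0)))

  g <- a$gains
  expect_equal(g$A_x[1, ], c(1.2173, 0.4060))
  expect_equal(g$B_y[2, ], c(0.8342, 0.3887))
})

test_that("the second example's printed matrices and constant delays", {
  e <- grn_example("4.2")
  expect_equal(e$model$B, matrix(c(-0.5, 2.5, 0, 0), 2, 2))
  expect_equal(e$model$L_x, diag(c(0.3, 0.4)))
  expect_equal(e$model$D, diag(c(0.08, 0.2)))
  ks <- 0:10
  expect_true(all(vapply(ks, e$schedule$delta, numeric(1)) == 2))
  expect_true(all(vapply(ks, e$schedule$tau, numeric(1)) == 1))
  expect_gte(e$model$delta_m, 0)
  expect_lte(2, e$model$delta_M)
})

test_that("trigonometric delay schedules take the printed values", {
  fx <- grn_example("4.1a")
  d <- vapply(0:7, fx$schedule$delta, numeric(1))
  expect_equal(round(d), c(3, 5, 3, 1, 3, 5, 3, 1))
})

test_that("fixtures round-trip bit-exactly through the config serializer", {
  for (nm in c("4.1a", "4.1b", "4.2")) {
    fx <- grn_example(nm)
    f <- tempfile(fileext = ".json")
    write_grn_config(fx$model, f)
    back <- read_grn_config(f)
    for (field in c("A", "B", "C", "D", "E", "F", "H", "L_x", "L_y",
                    "M", "N", "sigma")) {
      expect_identical(back[[field]], fx$model[[field]])
    }
    expect_identical(back$alpha0, fx$model$alpha0)
    expect_identical(back$hill, fx$model$hill)
    if (!is.null(fx$model$uncertainty)) {
      expect_identical(back$uncertainty$R, fx$model$uncertainty$R)
      expect_identical(back$uncertainty$W4, fx$model$uncertainty$W4)
    }
    unlink(f)
  }
})

test_that("the printed feasible solution violates the recovery relation", {
  # R21^{-1} X1 computed from the printed matrices does not reproduce the
  # printed gain A_x, which is why no computation relies on these values
  ps <- printed_solution_41()
  Ax_implied <- solve(ps$R21, ps$X1)
  Ax_printed <- grn_example("4.1b")$gains$A_x
  expect_gt(max(abs(Ax_implied - Ax_printed)), 0.1)
})

test_that("random stable models are deterministic contractions", {
  m1 <- random_stable_model(42, n = 3, target_contraction = 0.3)
  m2 <- random_stable_model(42, n = 3, target_contraction = 0.3)
  expect_identical(m1$B, m2$B)
  expect_identical(m1$H, m2$H)

  for (s in 1:5) {
    m <- random_stable_model(s, n = 2, target_contraction = 0.3)
    expect_lte(linearization_radius(m), 0.3 + 1e-9)
    ev <- eigen(m$H, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_true(all(diag(m$A) > 0 & diag(m$A) < 0.3))
  }
  expect_error(random_stable_model(1, n = 0), "at least 1")
  expect_error(random_stable_model(1, target_contraction = 1.5), "0, 1")
})
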