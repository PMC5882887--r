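# LMI assembly: block dimensions, symmetry, affinity, the structural
# relations between the four forms, and gain recovery.

random_values <- function(pb, seed = 1) {
  set.seed(seed)
  vals <- unpack_theta(pb$varmap, rnorm(pb$varmap$p))
  # make the sym variables meaningful PD-ish where relevant
  for (e in pb$varmap$entries) {
    if (e$kind == "sym") {
      v <- vals[[e$name]]
      vals[[e$name]] <- crossprod(v) + diag(0.1, e$nr)
    }
    if (e$kind == "scalar") vals[[e$name]] <- abs(vals[[e$name]]) + 0.1
  }
  vals
}

test_that("assembled dimensions follow the block counting", {
  fx <- grn_example("4.1b")
  pa <- assemble_analysis(fx$model, fx$gains, fx$sector)
  expect_equal(pa$dim1, 38)  # (7 + 5 + 7) blocks of size 2
  expect_equal(pa$dim2, 46)  # (9 + 5 + 9) blocks of size 2
  ph <- assemble_hinf(fx$model, fx$gains, fx$sector, gamma = 2)
  expect_equal(ph$dim1, 40)  # one extra disturbance block
  expect_equal(ph$dim2, 48)
  ps <- assemble_synthesis(fx$model, fx$sector, gamma = 2)
  expect_equal(c(ps$dim1, ps$dim2), c(40, 48))
})

test_that("assembly is symmetric at arbitrary variable values", {
  fx <- grn_example("4.1b")
  for (fid in c("paper", "repaired")) {
    pb <- assemble_synthesis(fx$model, fx$sector, gamma = 2,
                             fidelity = fid)
    L <- lmi_matrices(pb, random_values(pb, 3))
    expect_lte(max(abs(L$L1 - t(L$L1))), 1e-12)
    expect_lte(max(abs(L$L2 - t(L$L2))), 1e-12)
  }
})

test_that("assembly is affine in the decision variables", {
  fx <- grn_example("4.1b")
  pb <- assemble_synthesis(fx$model, fx$sector, gamma = 2)
  p <- pb$varmap$p
  set.seed(5)
  t1 <- rnorm(p); t2 <- rnorm(p); dt <- rnorm(p)
  ev <- function(th) lmi_matrices(pb, unpack_theta(pb$varmap, th))
  # finite differences of an affine map are base-point independent
  d_at_t1 <- ev(t1 + dt)$L1 - ev(t1)$L1
  d_at_t2 <- ev(t2 + dt)$L1 - ev(t2)$L1
  expect_lte(max(abs(d_at_t1 - d_at_t2)), 1e-10)
  d_at_t1 <- ev(t1 + dt)$L2 - ev(t1)$L2
  d_at_t2 <- ev(t2 + dt)$L2 - ev(t2)$L2
  expect_lte(max(abs(d_at_t1 - d_at_t2)), 1e-10)
})

test_that("certain measurements zero the variance rows", {
  m <- toy_model(2)
  m1 <- grn_model(A = m$A, B = m$B, C = m$C, D = m$D, E = m$E, F = m$F,
                  H = m$H, L_x = m$L_x, L_y = m$L_y, M = m$M, N = m$N,
                  rho1 = m$rho1, rho2 = m$rho2,
                  delta_m = m$delta_m, delta_M = m$delta_M,
                  tau_m = m$tau_m, tau_M = m$tau_M,
                  mu_kernel = m$mu_kernel, xi_kernel = m$xi_kernel,
                  alpha0 = 1, beta0 = 1, hill = 2, sigma = m$sigma,
                  uncertainty = m$uncertainty)
  pb <- assemble_analysis(m1, zero_gains(2), default_sector2())
  expect_equal(pb$sigma_alpha, 0)
  vals <- random_values(pb, 7)
  vals$R21 <- diag(2)  # nonzero gains row would otherwise be invisible
  g1 <- grn_gains(diag(0.1, 2), diag(0.2, 2), diag(0.1, 2), diag(0.2, 2))
  pb1 <- assemble_analysis(m1, g1, default_sector2())
  L <- lmi_matrices(pb1, vals)
  # variance row of S1 is block row 3 of the coupling region: rows 7n+2n+1..
  n <- 2; o_j <- 7 * n + 2 * n
  expect_true(all(L$L1[(o_j + 1):(o_j + n), 1:(7 * n)] == 0))
})

test_that("uncertainty-free analysis reduces to the nominal corollary", {
  m <- random_stable_model(6, n = 2, with_uncertainty = FALSE)
  sec <- default_sector2()
  g <- grn_gains(diag(0.1, 2), diag(0.2, 2), diag(0.1, 2), diag(0.2, 2))
  pa <- assemble_analysis(m, g, sec, fidelity = "paper")
  pn <- assemble_nominal(m, g, sec, fidelity = "paper")
  vals <- random_values(pa, 11)
  La <- lmi_matrices(pa, vals)
  Ln <- lmi_matrices(pn, vals)
  core1 <- 1:(12 * 2)  # Lambda'_11 and coupling regions: (7+5) blocks
  core2 <- 1:(14 * 2)
  expect_equal(La$L1[core1, core1], Ln$L1[core1, core1])
  expect_equal(La$L2[core2, core2], Ln$L2[core2, core2])
  # analysis corner is -eps1 I, nominal corner is the printed +I
  n1 <- pa$dim1
  expect_equal(La$L1[n1, n1], -vals$eps1)
  expect_equal(Ln$L1[n1, n1], 1)
  expect_error(assemble_nominal(grn_example("4.1b")$model, g, sec),
               "without uncertainty")
})

test_that("deleting the disturbance block reproduces the analysis form", {
  fx <- grn_example("4.1b")
  pa <- assemble_analysis(fx$model, fx$gains, fx$sector,
                          fidelity = "paper")
  ph <- assemble_hinf(fx$model, fx$gains, fx$sector, gamma = 3,
                      fidelity = "paper")
  vals <- random_values(pa, 13)
  La <- lmi_matrices(pa, vals)
  Lh <- lmi_matrices(ph, vals)
  n <- 2
  keep1 <- setdiff(seq_len(ph$dim1), 7 * n + seq_len(n))
  keep2 <- setdiff(seq_len(ph$dim2), 9 * n + seq_len(n))
  expect_equal(Lh$L1[keep1, keep1], La$L1)
  expect_equal(Lh$L2[keep2, keep2], La$L2)
  # the deleted diagonal block is -gamma^2 I
  expect_equal(Lh$L1[7 * n + 1, 7 * n + 1], -9)
})

test_that("synthesis reproduces the gain form under substitution", {
  fx <- grn_example("4.1b")
  for (fid in c("paper", "repaired")) {
    ps <- assemble_synthesis(fx$model, fx$sector, gamma = 2,
                             fidelity = fid)
    vals <- random_values(ps, 17)
    # recover gains from the substitution and re-assemble with them
    gains <- recover_gains(list(values = vals))
    ph <- assemble_hinf(fx$model, gains, fx$sector, gamma = 2,
                        fidelity = fid)
    Ls <- lmi_matrices(ps, vals)
    Lh <- lmi_matrices(ph, vals)
    expect_lte(max(abs(Ls$L1 - Lh$L1)), 1e-9 * max(1, max(abs(Ls$L1))))
    expect_lte(max(abs(Ls$L2 - Lh$L2)), 1e-9 * max(1, max(abs(Ls$L2))))
  }
})

test_that("gain recovery solves the linear systems", {
  X1 <- matrix(c(1, 2, 3, 4), 2, 2)
  g <- recover_gains(list(values = list(
    R21 = diag(2), R22 = diag(2), X1 = X1, X2 = diag(2),
    Y1 = diag(2), Y2 = diag(2))))
  expect_equal(g$A_x, X1)
  g2 <- recover_gains(list(values = list(
    R21 = 2 * diag(2), R22 = diag(2), X1 = X1, X2 = diag(2),
    Y1 = diag(2), Y2 = diag(2))))
  expect_equal(g2$B_x, 0.5 * diag(2))

  set.seed(21)
  S <- matrix(rnorm(9), 3, 3)
  R21 <- crossprod(S) + diag(3)
  X <- matrix(rnorm(9), 3, 3)
  g3 <- recover_gains(list(values = list(
    R21 = R21, R22 = diag(3), X1 = X, X2 = diag(3),
    Y1 = diag(3), Y2 = diag(3))))
  dense <- qr.solve(R21, X)  # independent dense solve
  expect_lte(max(abs(g3$A_x - dense)), 1e-10)

  near_sing <- diag(c(1, 1e-12))
  expect_error(recover_gains(list(values = list(
    R21 = near_sing, R22 = diag(2), X1 = diag(2), X2 = diag(2),
    Y1 = diag(2), Y2 = diag(2)))), "condition")
})

test_that("Schur equivalence oracle on scalars and random instances", {
  expect_true(schur_equivalence(matrix(-1), matrix(1), matrix(0)))
  expect_false(schur_equivalence(matrix(-1), matrix(1), matrix(2)))
  expect_error(schur_equivalence(matrix(-1), matrix(-1), matrix(0)),
               "positive definite")

  set.seed(31)
  for (i in 1:200) {
    m <- sample(1:6, 1); q <- sample(1:6, 1)
    O1 <- matrix(rnorm(m * m), m); O1 <- (O1 + t(O1)) / 2 - diag(0.5, m)
    S <- matrix(rnorm(q * q), q)
    O2 <- crossprod(S) + diag(0.1, q)
    O3 <- matrix(rnorm(q * m), q, m)
    expect_silent(schur_equivalence(O1, O2, O3))
  }
})
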