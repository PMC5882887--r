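# Assembly of the Lyapunov-Krasovskii block LMIs for the estimation error
# dynamics: the stability analysis form, the H-infinity form with a
# disturbance attenuation level, the gain-synthesis form with linearizing
# variable changes, and the nominal (uncertainty-free) corollary form.
#
# Two fidelity readings are exposed. "paper" assembles every diagonal block
# with its printed sign; in that reading several diagonal blocks (the
# noise-bound block H*R11, the distributed-state blocks (R12+R22) and
# (R11+R21), the kernel block mu_bar*R51, and the all-zero y-leakage block)
# are forced non-negative by the positive-definiteness of the decision
# matrices, so the matrices can never be negative definite: the assembler
# records these blocks and the solver reports certified infeasibility with
# that diagnosis. "repaired" flips those blocks to their negated symmetric
# forms so the conditions are satisfiable; it is an interpretation and is
# recorded as such on the problem object.

.lmi_varmap <- function(n, l, mode) {
  syms <- c("R11", "R12", "R21", "R22", "R31", "R32", "R41", "R42",
            "R51", "R52")
  entries <- lapply(syms, function(nm) {
    list(name = nm, kind = "sym", nr = n, nc = n, len = n * (n + 1) / 2)
  })
  scalars <- if (mode == "nominal") "lam" else c("lam", "eps1", "eps2")
  entries <- c(entries, lapply(scalars, function(nm) {
    list(name = nm, kind = "scalar", nr = 1, nc = 1, len = 1)
  }))
  if (mode == "synthesis") {
    entries <- c(entries, list(
      list(name = "X1", kind = "full", nr = n, nc = n, len = n * n),
      list(name = "X2", kind = "full", nr = n, nc = l, len = n * l),
      list(name = "Y1", kind = "full", nr = n, nc = n, len = n * n),
      list(name = "Y2", kind = "full", nr = n, nc = l, len = n * l)))
  }
  off <- 0
  for (i in seq_along(entries)) {
    entries[[i]]$offset <- off
    off <- off + entries[[i]]$len
  }
  structure(list(entries = entries, p = off), class = "grn_varmap")
}

.vech <- function(m) m[lower.tri(m, diag = TRUE)]

.unvech <- function(v, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m, diag = TRUE)] <- v
  m + t(m) - diag(diag(m), n)
}

#' @keywords internal
pack_theta <- function(varmap, values) {
  th <- numeric(varmap$p)
  for (e in varmap$entries) {
    v <- values[[e$name]]
    if (is.null(v)) next
    th[e$offset + seq_len(e$len)] <- switch(e$kind,
      sym = .vech(as.matrix(v)),
      full = as.numeric(v),
      scalar = as.numeric(v))
  }
  th
}

#' @keywords internal
unpack_theta <- function(varmap, theta) {
  out <- list()
  for (e in varmap$entries) {
    v <- theta[e$offset + seq_len(e$len)]
    out[[e$name]] <- switch(e$kind,
      sym = .unvech(v, e$nr),
      full = matrix(v, e$nr, e$nc),
      scalar = v)
  }
  out
}

# Shared assembler. `gains` is NULL in synthesis mode (the X/Y variables
# stand in for R21*Ax etc.); `gamma` is NULL in analysis/nominal modes.
.grn_assemble <- function(model, sector, mode, fidelity, gains = NULL,
                          gamma = NULL) {
  stopifnot(inherits(model, "grn_model"), inherits(sector, "grn_sector"))
  fidelity <- match.arg(fidelity, c("repaired", "paper"))
  n <- model$n; l <- model$l
  if (sector$n != n) stop("sector dimension mismatch", call. = FALSE)
  if (mode %in% c("analysis", "hinf", "nominal")) {
    stopifnot(inherits(gains, "grn_gains"))
    if (gains$n != n || gains$l != l) {
      stop("gain dimensions do not match the model", call. = FALSE)
    }
  }
  if (mode %in% c("hinf", "synthesis")) {
    if (is.null(gamma) || gamma <= 0) {
      stop("'gamma' must be a positive attenuation level", call. = FALSE)
    }
  }
  if (mode == "nominal" && !is.null(model$uncertainty)) {
    stop("the nominal form requires a model without uncertainty",
         call. = FALSE)
  }

  unc <- model$uncertainty
  Tm <- if (is.null(unc)) matrix(0, n, n) else unc$R
  W <- lapply(seq_len(6), function(i) {
    if (is.null(unc)) matrix(0, n, n) else unc[[paste0("W", i)]]
  })

  mu_bar <- kernel_mass(model$mu_kernel)
  xi_bar <- kernel_mass(model$xi_kernel)
  sa <- model$alpha0 * (1 - model$alpha0)
  sb <- model$beta0 * (1 - model$beta0)
  s2 <- sqrt(2)
  In <- diag(n)

  has_gamma <- mode %in% c("hinf", "synthesis")
  # region offsets within Lambda_1 / Lambda_2
  p1a <- 7L * n; p1b <- 9L * n
  q <- if (has_gamma) n else 0L
  p2 <- 5L * n
  dim1 <- p1a + q + p2 + p1a
  dim2 <- p1b + q + p2 + p1b

  varmap <- .lmi_varmap(n, l, mode)

  sym2 <- function(m) (m + t(m)) / 2
  rng <- function(off, i) (off + (i - 1L) * n + 1L):(off + i * n)
  rep_sign <- if (fidelity == "repaired") -1 else 1

  eval_fun <- function(values) {
    R11 <- values$R11; R12 <- values$R12; R21 <- values$R21
    R22 <- values$R22; R31 <- values$R31; R32 <- values$R32
    R41 <- values$R41; R42 <- values$R42; R51 <- values$R51
    R52 <- values$R52
    lam <- values$lam
    eps1 <- if (mode == "nominal") 0 else values$eps1
    eps2 <- if (mode == "nominal") 0 else values$eps2
    Rsum1 <- R11 + R21
    Rsum2 <- R12 + R22

    # linearized or gain-carrying estimator blocks
    if (mode == "synthesis") {
      P1 <- values$X1                      # stands for R21 Ax
      P2 <- values$X2 %*% model$M          # stands for R21 Bx M
      Q1 <- values$Y1                      # stands for R22 Ay
      Q2 <- values$Y2 %*% model$N          # stands for R22 By N
    } else {
      P1 <- R21 %*% gains$A_x
      P2 <- R21 %*% gains$B_x %*% model$M
      Q1 <- R22 %*% gains$A_y
      Q2 <- R22 %*% gains$B_y %*% model$N
    }

    # in the repaired H-infinity/synthesis reading the output-energy
    # identity contributes +I on the current-state and error coordinates
    out_I <- if (has_gamma && fidelity == "repaired") In else 0 * In

    ## ---- Lambda'_11 (7 diagonal blocks) ----
    D1 <- vector("list", 7)
    D1[[1]] <- -R11 + R31 + (model$tau_M - model$tau_m + 1) * R41 +
      xi_bar * R52 + out_I
    D1[[2]] <- -R21 + out_I
    D1[[3]] <- -R31
    D1[[4]] <- -R41 + eps1 * crossprod(W[[4]])
    D1[[5]] <- rep_sign * sym2(model$H %*% R11)
    D1[[6]] <- rep_sign * Rsum2
    D1[[7]] <- -xi_bar * R52

    ## ---- Lambda'_22 (9 diagonal blocks + sector coupling) ----
    D2 <- vector("list", 9)
    D2[[1]] <- -R12 + R32 + (model$delta_M - model$delta_m + 1) * R42 +
      out_I
    D2[[2]] <- -R22 + out_I
    D2[[3]] <- -R32
    D2[[4]] <- -R42 - lam * sector$Ntilde1 + eps2 * crossprod(W[[2]])
    D2[[5]] <- -lam * In
    D2[[6]] <- if (fidelity == "repaired") -Rsum2 else matrix(0, n, n)
    D2[[7]] <- rep_sign * Rsum1
    D2[[8]] <- rep_sign * mu_bar * R51
    D2[[9]] <- -mu_bar * R51

    ## ---- S_1 (5 x 7 blocks) ----
    S1 <- matrix(0, p2, p1a)
    sput <- function(S, i, j, blk) {
      S[((i - 1L) * n + 1L):(i * n), ((j - 1L) * n + 1L):(j * n)] <- blk
      S
    }
    S1 <- sput(S1, 1, 5, -s2 * Rsum1 %*% model$A)
    S1 <- sput(S1, 2, 1, s2 * (P1 - model$alpha0 * P2))
    S1 <- sput(S1, 2, 2, -s2 * P1)
    S1 <- sput(S1, 2, 3, -s2 * (1 - model$alpha0) * P2)
    S1 <- sput(S1, 3, 1, sqrt(sa) * P2)
    S1 <- sput(S1, 3, 3, sqrt(sa) * P2)
    S1 <- sput(S1, 4, 4, s2 * Rsum2 %*% model$D)
    S1 <- sput(S1, 5, 6, s2 * Rsum2 %*% model$F)

    ## ---- S_2 (5 x 9 blocks) ----
    S2 <- matrix(0, p2, p1b)
    S2 <- sput(S2, 1, 6, -s2 * Rsum2 %*% model$C)
    S2 <- sput(S2, 2, 1, s2 * (Q1 - model$beta0 * Q2))
    S2 <- sput(S2, 2, 2, -s2 * Q1)
    S2 <- sput(S2, 2, 3, -s2 * (1 - model$beta0) * Q2)
    S2 <- sput(S2, 3, 1, sqrt(sb) * Q2)
    S2 <- sput(S2, 3, 3, sqrt(sb) * Q2)
    S2 <- sput(S2, 4, 5, s2 * Rsum1 %*% model$B)
    S2 <- sput(S2, 5, 7, s2 * Rsum1 %*% model$E)

    ## ---- J_1, J_2 ----
    J1 <- matrix(0, p2, p2)
    J2 <- matrix(0, p2, p2)
    j1b <- list(-Rsum1, -R21, -R21, -Rsum2, -Rsum2)
    j2b <- list(-Rsum2, -R22, -R22, -Rsum1, -Rsum1)
    for (i in 1:5) {
      J1[((i - 1) * n + 1):(i * n), ((i - 1) * n + 1):(i * n)] <- j1b[[i]]
      J2[((i - 1) * n + 1):(i * n), ((i - 1) * n + 1):(i * n)] <- j2b[[i]]
    }

    ## ---- Tbar_1, Tbar_2 ----
    T1b <- matrix(0, p2, p1a)
    T1b <- sput(T1b, 1, 5, -s2 * Rsum1 %*% Tm)
    T1b <- sput(T1b, 4, 4, s2 * Rsum2 %*% Tm)
    T1b <- sput(T1b, 5, 6, s2 * Rsum2 %*% Tm)
    T2b <- matrix(0, p2, p1b)
    T2b <- sput(T2b, 1, 6, -s2 * Rsum2 %*% Tm)
    T2b <- sput(T2b, 4, 5, s2 * Rsum1 %*% Tm)
    T2b <- sput(T2b, 5, 7, s2 * Rsum1 %*% Tm)

    ## ---- place everything ----
    L1 <- matrix(0, dim1, dim1)
    L2 <- matrix(0, dim2, dim2)
    for (i in 1:7) L1[rng(0L, i), rng(0L, i)] <- D1[[i]]
    for (i in 1:9) L2[rng(0L, i), rng(0L, i)] <- D2[[i]]
    L2[rng(0L, 4), rng(0L, 5)] <- -lam * t(sector$Ntilde2)
    L2[rng(0L, 5), rng(0L, 4)] <- -lam * sector$Ntilde2

    o_g1 <- p1a; o_g2 <- p1b
    if (has_gamma) {
      L1[(o_g1 + 1):(o_g1 + n), (o_g1 + 1):(o_g1 + n)] <- -gamma^2 * In
      L2[(o_g2 + 1):(o_g2 + n), (o_g2 + 1):(o_g2 + n)] <- -gamma^2 * In
    }
    # disturbance couplings of the repaired reading: the L v term of the
    # state and error updates enters the two dynamics rows of S_1 / S_2
    if (has_gamma && fidelity == "repaired") {
      V1 <- matrix(0, p2, n)
      V1[1:n, ] <- s2 * Rsum1 %*% model$L_x
      V1[(n + 1):(2 * n), ] <- s2 * R21 %*% model$L_x
      V2 <- matrix(0, p2, n)
      V2[1:n, ] <- s2 * Rsum2 %*% model$L_y
      V2[(n + 1):(2 * n), ] <- s2 * R22 %*% model$L_y
    } else {
      V1 <- V2 <- NULL
    }
    o_j1 <- p1a + q; o_j2 <- p1b + q
    if (!is.null(V1)) {
      L1[(o_j1 + 1):(o_j1 + p2), (o_g1 + 1):(o_g1 + n)] <- V1
      L1[(o_g1 + 1):(o_g1 + n), (o_j1 + 1):(o_j1 + p2)] <- t(V1)
      L2[(o_j2 + 1):(o_j2 + p2), (o_g2 + 1):(o_g2 + n)] <- V2
      L2[(o_g2 + 1):(o_g2 + n), (o_j2 + 1):(o_j2 + p2)] <- t(V2)
    }
    L1[(o_j1 + 1):(o_j1 + p2), 1:p1a] <- S1
    L1[1:p1a, (o_j1 + 1):(o_j1 + p2)] <- t(S1)
    L1[(o_j1 + 1):(o_j1 + p2), (o_j1 + 1):(o_j1 + p2)] <- J1
    L2[(o_j2 + 1):(o_j2 + p2), 1:p1b] <- S2
    L2[1:p1b, (o_j2 + 1):(o_j2 + p2)] <- t(S2)
    L2[(o_j2 + 1):(o_j2 + p2), (o_j2 + 1):(o_j2 + p2)] <- J2

    o_c1 <- p1a + q + p2; o_c2 <- p1b + q + p2
    if (mode == "nominal") {
      cc <- if (fidelity == "repaired") -1 else 1
      L1[(o_c1 + 1):(o_c1 + p1a), (o_c1 + 1):(o_c1 + p1a)] <-
        cc * diag(p1a)
      L2[(o_c2 + 1):(o_c2 + p1b), (o_c2 + 1):(o_c2 + p1b)] <-
        cc * diag(p1b)
    } else {
      L1[(o_c1 + 1):(o_c1 + p1a), (o_j1 + 1):(o_j1 + p2)] <- t(T1b)
      L1[(o_j1 + 1):(o_j1 + p2), (o_c1 + 1):(o_c1 + p1a)] <- T1b
      L1[(o_c1 + 1):(o_c1 + p1a), (o_c1 + 1):(o_c1 + p1a)] <-
        -eps1 * diag(p1a)
      L2[(o_c2 + 1):(o_c2 + p1b), (o_j2 + 1):(o_j2 + p2)] <- t(T2b)
      L2[(o_j2 + 1):(o_j2 + p2), (o_c2 + 1):(o_c2 + p1b)] <- T2b
      L2[(o_c2 + 1):(o_c2 + p1b), (o_c2 + 1):(o_c2 + p1b)] <-
        -eps2 * diag(p1b)
    }
    list(L1 = L1, L2 = L2)
  }

  forced <- if (fidelity == "paper") {
    fp <- c("Lambda1: noise-bound diagonal block sym(H R11) (positive trace for PD R11)",
            "Lambda1: distributed-state diagonal block (R12+R22) (PD)",
            "Lambda2: y-leakage diagonal block is identically zero",
            "Lambda2: distributed-state diagonal block (R11+R21) (PD)")
    if (mu_bar > 0) {
      fp <- c(fp, "Lambda2: kernel diagonal block mu_bar*R51 (PD scaled)")
    }
    if (mode == "nominal") {
      fp <- c(fp, "corner diagonal block +I (positive definite as printed)")
    }
    fp
  } else {
    character(0)
  }

  layout <- list(
    Lambda1 = list(state_blocks = 7L, gamma_block = has_gamma,
                   coupling_blocks = 5L, uncertainty_corner = p1a,
                   dim = dim1,
                   coordinates = c("x(k)", "xerr(k)", "x(k-1)",
                                   "x(k-tau(k))", "x(k-rho1)",
                                   "x distributed", "x distributed (scaled)")),
    Lambda2 = list(state_blocks = 9L, gamma_block = has_gamma,
                   coupling_blocks = 5L, uncertainty_corner = p1b,
                   dim = dim2,
                   coordinates = c("y(k)", "yerr(k)", "y(k-1)",
                                   "y(k-delta(k))", "g(y(k-delta(k)))",
                                   "y(k-rho2)", "y distributed",
                                   "h distributed", "h distributed (scaled)")))

  structure(list(
    mode = mode, fidelity = fidelity, n = n, l = l,
    model = model, sector = sector, gains = gains, gamma = gamma,
    mu_bar = mu_bar, xi_bar = xi_bar,
    sigma_alpha = sa, sigma_beta = sb,
    varmap = varmap, layout = layout,
    dim1 = dim1, dim2 = dim2,
    eval = eval_fun,
    forced_positive = forced), class = "grn_lmi")
}

#' Assemble the stability-analysis LMIs
#'
#' Builds the pair of symmetric block matrices whose simultaneous negative
#' definiteness certifies robust mean-square exponential stability of the
#' estimation error dynamics for *given* estimator gains (no disturbance
#' channel). Decision variables are the ten positive definite matrices
#' `R11..R52` and the scalars `lam`, `eps1`, `eps2`; the gains enter as
#' data, so every block is affine in the decision variables.
#'
#' @param model a [grn_model()].
#' @param gains a [grn_gains()] record.
#' @param sector a [sector_bounds()] object.
#' @param fidelity `"repaired"` (satisfiable sign reading, default) or
#'   `"paper"` (printed signs; structurally infeasible, reported with an
#'   analytic diagnosis).
#' @return an object of class `grn_lmi`.
#' @export
assemble_analysis <- function(model, gains, sector,
                              fidelity = c("repaired", "paper")) {
  .grn_assemble(model, sector, "analysis", match.arg(fidelity),
                gains = gains)
}

#' Assemble the H-infinity performance LMIs
#'
#' As [assemble_analysis()] but with the disturbance channel retained: each
#' matrix gains one diagonal block `-gamma^2 I`, and feasibility certifies
#' disturbance attenuation at level `gamma` in addition to stability.
#' Deleting the disturbance block row/column reproduces the analysis form
#' entrywise.
#'
#' @inheritParams assemble_analysis
#' @param gamma disturbance attenuation level (> 0).
#' @return an object of class `grn_lmi`.
#' @export
assemble_hinf <- function(model, gains, sector, gamma,
                          fidelity = c("repaired", "paper")) {
  .grn_assemble(model, sector, "hinf", match.arg(fidelity),
                gains = gains, gamma = gamma)
}

#' Assemble the gain-synthesis LMIs
#'
#' The H-infinity form with the estimator gains eliminated through the
#' linearizing change of variables `X1 = R21 Ax`, `X2 = R21 Bx`,
#' `Y1 = R22 Ay`, `Y2 = R22 By`: the problem becomes jointly affine in all
#' decision variables, and gains are recovered afterwards with
#' [recover_gains()].
#'
#' @inheritParams assemble_hinf
#' @return an object of class `grn_lmi`.
#' @export
assemble_synthesis <- function(model, sector, gamma,
                               fidelity = c("repaired", "paper")) {
  .grn_assemble(model, sector, "synthesis", match.arg(fidelity),
                gamma = gamma)
}

#' Assemble the nominal (uncertainty-free) stability LMIs
#'
#' The corollary form for the network without parameter uncertainty: the
#' uncertainty corner is replaced by a constant identity block (sign per
#' fidelity) and the scalars `eps1`, `eps2` drop out. Requires a model with
#' no uncertainty structure.
#'
#' @inheritParams assemble_analysis
#' @return an object of class `grn_lmi`.
#' @export
assemble_nominal <- function(model, gains, sector,
                             fidelity = c("repaired", "paper")) {
  .grn_assemble(model, sector, "nominal", match.arg(fidelity),
                gains = gains)
}

#' Evaluate the assembled matrices at given decision-variable values
#'
#' @param problem a `grn_lmi` from one of the `assemble_*` functions.
#' @param values named list of decision-variable values (`R11` ... `R52`,
#'   `lam`, `eps1`, `eps2`, and `X1`, `X2`, `Y1`, `Y2` in synthesis mode).
#' @return list with symmetric matrices `L1`, `L2`.
#' @export
lmi_matrices <- function(problem, values) {
  stopifnot(inherits(problem, "grn_lmi"))
  problem$eval(values)
}

#' @export
print.grn_lmi <- function(x, ...) {
  cat(sprintf("<grn_lmi> mode %s, fidelity %s: Lambda1 %dx%d, Lambda2 %dx%d, %d decision scalars\n",
              x$mode, x$fidelity, x$dim1, x$dim1, x$dim2, x$dim2,
              x$varmap$p))
  if (length(x$forced_positive)) {
    cat("  positive-forced diagonal blocks (printed reading):\n")
    for (f in x$forced_positive) cat("   -", f, "\n")
  }
  invisible(x)
}

# Affine decomposition M(theta) = M0 + sum_j theta_j Mj for both assembled
# matrices; exact because assembly is affine in the decision variables.
.lmi_affine <- function(problem) {
  p <- problem$varmap$p
  base_vals <- unpack_theta(problem$varmap, numeric(p))
  m0 <- problem$eval(base_vals)
  coefs1 <- vector("list", p)
  coefs2 <- vector("list", p)
  for (j in seq_len(p)) {
    ej <- numeric(p); ej[j] <- 1
    mj <- problem$eval(unpack_theta(problem$varmap, ej))
    coefs1[[j]] <- mj$L1 - m0$L1
    coefs2[[j]] <- mj$L2 - m0$L2
  }
  list(base1 = m0$L1, base2 = m0$L2, coefs1 = coefs1, coefs2 = coefs2)
}
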