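# Forward simulation of the delayed stochastic GRN, the measurement channel
# with Bernoulli dropout, the state estimator, and the estimation-error
# recursion (propagated both directly and by subtraction, so the defining
# identity of the error dynamics is checkable on every run).

#' Time-varying delay schedule
#'
#' Wraps the integer-valued delay functions \eqn{\delta(k)} (feedback
#' regulation) and \eqn{\tau(k)} (translation). Values are validated against
#' the model's bounds at simulation time; non-integer values are rejected
#' rather than rounded (an absolute integrality tolerance of `1e-9` absorbs
#' floating-point noise in expressions such as `3 + 2*sin(k*pi/2)`).
#'
#' @param delta,tau functions of the time index `k`, or single integers for
#'   constant delays.
#' @return an object of class `grn_schedule`.
#' @export
grn_schedule <- function(delta, tau) {
  as_fun <- function(f) {
    if (is.function(f)) return(f)
    force(f); function(k) rep_len(f, length(k))
  }
  structure(list(delta = as_fun(delta), tau = as_fun(tau)),
            class = "grn_schedule")
}

.eval_schedule <- function(fun, ks, lo, hi, what) {
  v <- vapply(ks, fun, numeric(1))
  r <- round(v)
  if (any(abs(v - r) > 1e-9)) {
    stop(sprintf("%s(k) must be integer-valued (got %g at k = %d)",
                 what, v[which.max(abs(v - r))][1],
                 ks[which.max(abs(v - r))][1]), call. = FALSE)
  }
  r <- as.integer(r)
  if (any(r < lo) || any(r > hi)) {
    bad <- which(r < lo | r > hi)[1]
    stop(sprintf("%s(%d) = %d violates the bounds [%d, %d]",
                 what, ks[bad], r[bad], lo, hi), call. = FALSE)
  }
  r
}

# Partition one master seed into independent per-role streams so that
# toggling one noise source does not shift the draws of the others.
.role_seeds <- function(seed) {
  rs <- local_rng(seed)
  on.exit(rs())
  s <- sample.int(2147483646L, 4)
  names(s) <- c("omega", "alpha", "beta", "uncertainty")
  s
}

.draw_bernoulli <- function(n, p, seed) {
  rs <- local_rng(seed)
  on.exit(rs())
  as.numeric(runif(n) < p)
}

.draw_normal <- function(n, seed) {
  rs <- local_rng(seed)
  on.exit(rs())
  rnorm(n)
}

#' Simulate the GRN, its measurements, estimator, and error dynamics
#'
#' Integrates the delayed stochastic difference equations of the model
#' together with the dropout measurement channel
#' \eqn{\tilde Z_x(k) = \alpha_k Z_x(k) + (1-\alpha_k) Z_x(k-1)} and the
#' estimator \eqn{\hat x(k+1) = -A_x \hat x(k) + B_x \tilde Z_x(k)} (and the
#' protein analogues). The estimation error is propagated twice: by
#' subtraction \eqn{x - \hat x} and directly through the error recursion;
#' both records are returned so their agreement (an algebraic identity) can
#' be asserted.
#'
#' The infinite distributed-delay sums are truncated at relative tail mass
#' `rel_tol`; states before the supplied history window are taken as zero.
#'
#' @param model a [grn_model()].
#' @param gains a [grn_gains()] record.
#' @param schedule a [grn_schedule()].
#' @param horizon number of steps `K >= 1`.
#' @param seed master seed; partitioned into independent streams for the
#'   process noise, the two dropout sequences, and random uncertainty draws.
#' @param disturbance `NULL` for none, or a list with functions or
#'   `n x K` matrices `vx`, `vy` giving \eqn{v_x(k)}, \eqn{v_y(k)} for
#'   `k = 0, ..., K-1`.
#' @param noise `"on"` to include the multiplicative noise term
#'   \eqn{\sigma(k, x(k-\rho_1))\omega(k)}, `"off"` to drop it.
#' @param uncertainty_mode passed to [sample_uncertainty()].
#' @param history `NULL` for zero pre-history, `"random"` for seeded
#'   standard-uniform initial histories, or a list with `x`, `y` matrices of
#'   `n` rows whose last column is the state at `k = 0`.
#' @param xhat0,yhat0 estimator initial values (default zero).
#' @param rel_tol kernel truncation tolerance.
#' @return an object of class `grn_trajectory`: matrices `x`, `y`, `xhat`,
#'   `yhat`, `xerr`, `yerr` (columns `k = 0..K`), direct-error records
#'   `xerr_direct`, `yerr_direct`, measurements `Zx`, `Zy`, `Zx_tilde`,
#'   `Zy_tilde`, realized draws `alpha`, `beta`, `omega`, disturbances
#'   `vx`, `vy`, and the initial histories.
#' @export
simulate_grn <- function(model, gains, schedule, horizon,
                         seed = 1L,
                         disturbance = NULL,
                         noise = c("on", "off"),
                         uncertainty_mode = c("off", "paper-trig",
                                              "random-contraction"),
                         history = NULL,
                         xhat0 = NULL, yhat0 = NULL,
                         rel_tol = 1e-12) {
  noise <- match.arg(noise)
  uncertainty_mode <- match.arg(uncertainty_mode)
  stopifnot(inherits(model, "grn_model"), inherits(gains, "grn_gains"),
            inherits(schedule, "grn_schedule"))
  if (!is.numeric(horizon) || horizon < 1) {
    stop("'horizon' must be at least 1", call. = FALSE)
  }
  K <- as.integer(horizon)
  n <- model$n; l <- model$l
  if (gains$n != n || gains$l != l) {
    stop("gain dimensions do not match the model", call. = FALSE)
  }

  mu_tr <- truncate_kernel(model$mu_kernel, rel_tol)
  xi_tr <- truncate_kernel(model$xi_kernel, rel_tol)
  Smu <- mu_tr$s_max; Sxi <- xi_tr$s_max

  Lh <- max(model$tau_M, model$delta_M, model$rho1, model$rho2, Smu, Sxi, 1L)
  idx <- function(k) k + Lh + 1L  # column index for time k in -Lh..K

  ks <- 0:(K - 1L)
  del <- .eval_schedule(schedule$delta, ks, model$delta_m, model$delta_M,
                        "delta")
  tau <- .eval_schedule(schedule$tau, ks, model$tau_m, model$tau_M, "tau")

  seeds <- .role_seeds(seed)
  omega <- if (noise == "on") .draw_normal(K, seeds[["omega"]]) else
    numeric(K)
  alpha <- .draw_bernoulli(K, model$alpha0, seeds[["alpha"]])
  beta <- .draw_bernoulli(K, model$beta0, seeds[["beta"]])

  # disturbances as n x K matrices
  as_dist <- function(v) {
    if (is.null(v)) return(matrix(0, n, K))
    if (is.function(v)) {
      out <- vapply(ks, function(k) rep_len(v(k), n), numeric(n))
      return(matrix(out, n, K))
    }
    v <- as.matrix(v)
    if (nrow(v) != n || ncol(v) != K) {
      stop("disturbance matrices must be n x K", call. = FALSE)
    }
    v
  }
  vx <- as_dist(disturbance$vx)
  vy <- as_dist(disturbance$vy)

  X <- matrix(0, n, Lh + 1L + K)
  Y <- matrix(0, n, Lh + 1L + K)
  if (is.null(history)) {
    hist_x <- matrix(0, n, Lh + 1L)
    hist_y <- matrix(0, n, Lh + 1L)
  } else if (identical(history, "random")) {
    # random draws span only the model's delay window (independent of the
    # kernel truncation length); older states are zero, as for every
    # supplied history
    Hw <- max(model$tau_M, model$delta_M, model$rho1, model$rho2) + 1L
    Hw <- min(Hw, Lh + 1L)
    rs <- local_rng(seed + 92821L)
    hist_x <- cbind(matrix(0, n, Lh + 1L - Hw), matrix(runif(n * Hw), n))
    hist_y <- cbind(matrix(0, n, Lh + 1L - Hw), matrix(runif(n * Hw), n))
    rs()
  } else {
    pad <- function(h) {
      h <- as.matrix(h)
      if (nrow(h) != n) stop("history must have n rows", call. = FALSE)
      w <- ncol(h)
      if (w >= Lh + 1L) return(h[, (w - Lh):w, drop = FALSE])
      cbind(matrix(0, n, Lh + 1L - w), h)
    }
    hist_x <- pad(history$x)
    hist_y <- pad(history$y)
  }
  X[, seq_len(Lh + 1L)] <- hist_x
  Y[, seq_len(Lh + 1L)] <- hist_y

  Xhat <- matrix(0, n, Lh + 1L + K)
  Yhat <- matrix(0, n, Lh + 1L + K)
  if (!is.null(xhat0)) Xhat[, idx(0L)] <- xhat0
  if (!is.null(yhat0)) Yhat[, idx(0L)] <- yhat0

  # direct error recursion storage (k = 0..K)
  Exd <- matrix(0, n, K + 1L)
  Eyd <- matrix(0, n, K + 1L)
  Exd[, 1L] <- X[, idx(0L)] - Xhat[, idx(0L)]
  Eyd[, 1L] <- Y[, idx(0L)] - Yhat[, idx(0L)]

  Zx <- matrix(0, l, K)
  Zy <- matrix(0, l, K)
  Zxt <- matrix(0, l, K)
  Zyt <- matrix(0, l, K)

  A <- model$A; B <- model$B; C <- model$C; D <- model$D
  E <- model$E; F <- model$F
  Ax <- gains$A_x; Bx <- gains$B_x; Ay <- gains$A_y; By <- gains$B_y
  Sg <- model$sigma
  h <- model$hill
  gfun <- function(v) .hill_even(v, h)  # vectorized over matrix columns
  muw <- mu_tr$weights; xiw <- xi_tr$weights

  unc_seed <- seeds[["uncertainty"]]
  unc <- model$uncertainty
  mode_k <- if (is.null(unc)) "off" else uncertainty_mode

  for (k in ks) {
    j <- idx(k)
    xk <- X[, j]; yk <- Y[, j]
    x_rho <- X[, idx(k - model$rho1)]
    y_rho <- Y[, idx(k - model$rho2)]
    x_tau <- X[, idx(k - tau[k + 1L])]
    y_del <- Y[, idx(k - del[k + 1L])]

    d <- sample_uncertainty(unc, k, mode = mode_k, seed = unc_seed, n = n)

    g_del <- gfun(y_del)
    # distributed sums over the truncated past
    Ymat <- Y[, j - seq_len(Smu), drop = FALSE]
    dist_mu <- gfun(Ymat) %*% muw
    Xmat <- X[, j - seq_len(Sxi), drop = FALSE]
    dist_xi <- Xmat %*% xiw

    sig <- if (noise == "on") drop(Sg %*% x_rho) * omega[k + 1L] else
      numeric(n)

    x_next <- -(A + d$DeltaA) %*% x_rho + (B + d$DeltaB) %*% g_del +
      (E + d$DeltaE) %*% dist_mu + sig + model$L_x %*% vx[, k + 1L]
    y_next <- -(C + d$DeltaC) %*% y_rho + (D + d$DeltaD) %*% x_tau +
      (F + d$DeltaF) %*% dist_xi + model$L_y %*% vy[, k + 1L]
    X[, j + 1L] <- x_next
    Y[, j + 1L] <- y_next

    # measurement channel with one-step dropout
    zx <- model$M %*% xk
    zy <- model$N %*% yk
    zx_prev <- model$M %*% X[, j - 1L]
    zy_prev <- model$N %*% Y[, j - 1L]
    Zx[, k + 1L] <- zx
    Zy[, k + 1L] <- zy
    Zxt[, k + 1L] <- alpha[k + 1L] * zx + (1 - alpha[k + 1L]) * zx_prev
    Zyt[, k + 1L] <- beta[k + 1L] * zy + (1 - beta[k + 1L]) * zy_prev

    Xhat[, j + 1L] <- -Ax %*% Xhat[, j] + Bx %*% Zxt[, k + 1L]
    Yhat[, j + 1L] <- -Ay %*% Yhat[, j] + By %*% Zyt[, k + 1L]

    # direct error recursion
    Exd[, k + 2L] <- -(A + d$DeltaA) %*% x_rho +
      (Ax - alpha[k + 1L] * Bx %*% model$M) %*% xk +
      (B + d$DeltaB) %*% g_del + (E + d$DeltaE) %*% dist_mu + sig -
      Ax %*% Exd[, k + 1L] -
      (1 - alpha[k + 1L]) * Bx %*% model$M %*% X[, j - 1L] +
      model$L_x %*% vx[, k + 1L]
    Eyd[, k + 2L] <- -(C + d$DeltaC) %*% y_rho +
      (Ay - beta[k + 1L] * By %*% model$N) %*% yk +
      (D + d$DeltaD) %*% x_tau + (F + d$DeltaF) %*% dist_xi -
      Ay %*% Eyd[, k + 1L] -
      (1 - beta[k + 1L]) * By %*% model$N %*% Y[, j - 1L] +
      model$L_y %*% vy[, k + 1L]
  }

  cols <- idx(0L):idx(K)
  x <- X[, cols, drop = FALSE]
  y <- Y[, cols, drop = FALSE]
  xhat <- Xhat[, cols, drop = FALSE]
  yhat <- Yhat[, cols, drop = FALSE]
  structure(list(
    K = K, n = n, l = l,
    x = x, y = y, xhat = xhat, yhat = yhat,
    xerr = x - xhat, yerr = y - yhat,
    xerr_direct = Exd, yerr_direct = Eyd,
    Zx = Zx, Zy = Zy, Zx_tilde = Zxt, Zy_tilde = Zyt,
    alpha = alpha, beta = beta, omega = omega,
    vx = vx, vy = vy,
    delta = del, tau = tau,
    history_x = hist_x, history_y = hist_y,
    seed = seed, noise = noise, uncertainty_mode = mode_k),
    class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf("<grn_trajectory> n = %d, K = %d steps, noise %s, uncertainty %s\n",
              x$n, x$K, x$noise, x$uncertainty_mode))
  e <- colSums(x$x^2) + colSums(x$xerr^2) + colSums(x$y^2) +
    colSums(x$yerr^2)
  cat(sprintf("  |xbar|^2+|ybar|^2: start %.4g, end %.4g\n",
              e[1], e[length(e)]))
  invisible(x)
}

#' Export a trajectory as a data frame
#'
#' One row per time step `k = 0..K`, with one column per coordinate of the
#' states, estimates, errors and realized draws (documented column order:
#' `k`, `x.*`, `y.*`, `xhat.*`, `yhat.*`, `xerr.*`, `yerr.*`, `alpha`,
#' `beta`; the draws are `NA` at `k = K` where no transition was taken).
#'
#' @param traj a `grn_trajectory`.
#' @return a `data.frame`.
#' @export
trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "grn_trajectory"))
  K <- traj$K; n <- traj$n
  blk <- function(m, nm) {
    d <- as.data.frame(t(m))
    names(d) <- paste0(nm, ".", seq_len(n))
    d
  }
  cbind(data.frame(k = 0:K),
        blk(traj$x, "x"), blk(traj$y, "y"),
        blk(traj$xhat, "xhat"), blk(traj$yhat, "yhat"),
        blk(traj$xerr, "xerr"), blk(traj$yerr, "yerr"),
        data.frame(alpha = c(traj$alpha, NA), beta = c(traj$beta, NA)))
}
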