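# Ensemble statistics over simulated trajectories: the mean-square decay
# series with its fitted exponential rate, and the H-infinity energy ratio.

# |xbar(k)|^2 + |ybar(k)|^2 for one trajectory, where xbar stacks the true
# state and the estimation error (the augmented vector whose decay the
# exponential-stability definition bounds).
.traj_ms <- function(traj) {
  colSums(traj$x^2) + colSums(traj$xerr^2) +
    colSums(traj$y^2) + colSums(traj$yerr^2)
}

#' Ensemble mean-square series and fitted exponential decay
#'
#' Averages \eqn{|\bar x(k)|^2 + |\bar y(k)|^2} over an ensemble of
#' trajectories (\eqn{\bar x = (x, \tilde x)} the augmented state/error
#' vector) and fits the exponential envelope \eqn{\alpha \mu^k} by least
#' squares on the logarithm. The fit window starts after `burn_in` steps and
#' ends before the series reaches 100 machine epsilons relative to its peak
#' (so the log of the numerical noise floor is never fitted). A numeric
#' vector may be supplied in place of trajectories, in which case it is
#' taken as the mean-square series itself.
#'
#' @param trajectories list of `grn_trajectory` objects sharing a horizon
#'   (at least 2), or a numeric series indexed by `k = 0, 1, ...`.
#' @param burn_in steps dropped before fitting; default
#'   `max(delay bounds) + 1` when trajectories are supplied, else 0.
#' @param r2_threshold minimum R-squared of the log-linear fit for the decay
#'   factor to be reported (default 0.9).
#' @param conf confidence level for the decay-factor interval.
#' @return list with the series `ms` (named by `k`), fitted `mu` (decay
#'   factor per step), `alpha` (prefactor), `mu_ci` (interval), `r2`,
#'   `fit_window`, and `verdict` in `"stable"`, `"not-stable"`,
#'   `"inconclusive"`.
#' @export
ensemble_mean_square <- function(trajectories, burn_in = NULL,
                                 r2_threshold = 0.9, conf = 0.95) {
  if (is.numeric(trajectories)) {
    ms <- as.numeric(trajectories)
    if (is.null(burn_in)) burn_in <- 0L
  } else {
    if (length(trajectories) < 2) {
      stop("need at least 2 trajectories (or a numeric series)",
           call. = FALSE)
    }
    Ks <- vapply(trajectories, function(t) t$K, integer(1))
    if (length(unique(Ks)) != 1) {
      stop("trajectories must share a horizon", call. = FALSE)
    }
    ms <- rowMeans(vapply(trajectories, .traj_ms,
                          numeric(Ks[1] + 1L)))
    if (is.null(burn_in)) {
      t1 <- trajectories[[1]]
      burn_in <- max(attr(t1, "burn_in"), 0L, na.rm = TRUE)
    }
  }
  k <- seq_along(ms) - 1L
  out <- list(ms = setNames(ms, k))

  if (all(ms == 0)) {
    out$mu <- NA_real_; out$alpha <- NA_real_; out$mu_ci <- c(NA, NA)
    out$r2 <- NA_real_; out$fit_window <- integer(0)
    out$verdict <- "inconclusive"
    out$mu_undefined <- TRUE
    return(structure(out, class = "grn_decay_fit"))
  }

  floor_lvl <- 100 * .Machine$double.eps * max(ms)
  keep <- which(k >= burn_in & ms > floor_lvl)
  # stop at the first drop below the floor after burn-in
  if (length(keep)) {
    keep <- keep[seq_len(which.max(c(diff(keep) != 1L, TRUE)))]
  }
  if (length(keep) < 3) {
    out$mu <- NA_real_; out$alpha <- NA_real_; out$mu_ci <- c(NA, NA)
    out$r2 <- NA_real_; out$fit_window <- keep - 1L
    out$verdict <- "inconclusive"
    return(structure(out, class = "grn_decay_fit"))
  }

  kk <- k[keep]
  ll <- log(ms[keep])
  fit <- lm(ll ~ kk)
  slope <- coef(fit)[["kk"]]
  r2 <- suppressWarnings(summary(fit)$r.squared)
  # constant series: lm reports r2 = 0 but the envelope mu = 1 is exact
  if (isTRUE(all.equal(var(ll), 0))) r2 <- 1
  ci <- tryCatch(suppressWarnings(confint(fit, "kk", level = conf)),
                 error = function(e) matrix(c(slope, slope), 1))
  ci[!is.finite(ci)] <- slope
  out$mu <- exp(slope)
  out$alpha <- exp(coef(fit)[["(Intercept)"]])
  out$mu_ci <- exp(c(ci[1], ci[2]))
  out$r2 <- r2
  out$fit_window <- kk
  out$verdict <- if (r2 < r2_threshold) {
    "inconclusive"
  } else if (out$mu_ci[2] < 1) {
    "stable"
  } else {
    "not-stable"
  }
  structure(out, class = "grn_decay_fit")
}

#' @export
print.grn_decay_fit <- function(x, ...) {
  cat(sprintf("<decay fit> mu = %.6g (CI %.6g..%.6g), alpha = %.4g, R2 = %.4f, %s\n",
              x$mu, x$mu_ci[1], x$mu_ci[2], x$alpha, x$r2, x$verdict))
  invisible(x)
}

#' H-infinity energy ratio of an ensemble
#'
#' For trajectories driven from zero initial conditions by square-summable
#' disturbances, computes
#' \deqn{\frac{\sum_k \mathbb{E}\{|\bar x(k)|^2 + |\bar y(k)|^2\}}
#'   {\sum_k (|v_x(k)|^2 + |v_y(k)|^2)}}
#' (the expectation estimated by the ensemble mean). The attenuation claim
#' with level \eqn{\gamma} is that this ratio never exceeds
#' \eqn{\gamma^2}.
#'
#' @param trajectories list of `grn_trajectory` objects sharing a horizon
#'   and the same disturbance inputs; initial histories must be zero.
#' @return list with `ratio`, `energy_out`, `energy_in`.
#' @export
hinf_ratio <- function(trajectories) {
  if (length(trajectories) < 1) {
    stop("need at least 1 trajectory", call. = FALSE)
  }
  t1 <- trajectories[[1]]
  if (max(abs(t1$history_x), abs(t1$history_y)) != 0) {
    stop("H-infinity ratio is defined for zero initial conditions",
         call. = FALSE)
  }
  energy_in <- sum(t1$vx^2) + sum(t1$vy^2)
  if (energy_in == 0) {
    stop("disturbance energy is zero: the ratio is undefined",
         call. = FALSE)
  }
  ms <- rowMeans(vapply(trajectories, .traj_ms, numeric(t1$K + 1L)))
  energy_out <- sum(ms)
  list(ratio = energy_out / energy_in,
       energy_out = energy_out, energy_in = energy_in)
}

#' Partial sums bound for distributed-delay quadratic forms
#'
#' For a positive semi-definite matrix `M`, non-negative weights `a_i`, and
#' vectors `x_i`, the quadratic form of the weighted sum is dominated by the
#' weighted sum of quadratic forms:
#' \deqn{\Big(\sum_i a_i x_i\Big)^T M \Big(\sum_i a_i x_i\Big) \le
#'   \Big(\sum_i a_i\Big) \sum_i a_i x_i^T M x_i.}
#' This inequality is what lets the infinite distributed-delay sums enter
#' the stability analysis; it is exposed so that tests can check it on
#' random instances.
#'
#' @param M positive semi-definite matrix (n x n).
#' @param a non-negative weights (length m).
#' @param X matrix of stacked vectors (n x m), column `i` holding `x_i`.
#' @return list with `lhs`, `rhs`, and `slack = rhs - lhs` (non-negative up
#'   to round-off when the preconditions hold).
#' @export
series_square_bound <- function(M, a, X) {
  X <- as.matrix(X)
  a <- as.numeric(a)
  stopifnot(ncol(X) == length(a))
  if (any(a < 0)) stop("'a' must be non-negative", call. = FALSE)
  s <- drop(X %*% a)
  lhs <- drop(crossprod(s, M %*% s))
  rhs <- sum(a) * sum(a * colSums(X * (M %*% X)))
  list(lhs = lhs, rhs = rhs, slack = rhs - lhs)
}
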