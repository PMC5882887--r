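# Domain types for the delayed stochastic GRN model, the Hill regulation
# function with its sector machinery, and the norm-bounded uncertainty
# generator.

.as_matrix <- function(x, n, m, what) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) != n || ncol(x) != m) {
    stop(sprintf("'%s' must be a numeric %dx%d matrix", what, n, m),
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

.is_diagonal <- function(x, tol = 0) {
  all(abs(x[row(x) != col(x)]) <= tol)
}

.sym_check <- function(x, what, tol = 1e-10) {
  if (max(abs(x - t(x))) > tol * max(1, max(abs(x)))) {
    stop(sprintf("'%s' must be symmetric", what), call. = FALSE)
  }
  (x + t(x)) / 2
}

#' Construct a discrete-time stochastic GRN model
#'
#' Bundles every parameter of the delayed stochastic difference equations
#' governing mRNA concentrations `x(k)` and protein concentrations `y(k)`:
#' \deqn{x(k+1) = -(A+\Delta A)x(k-\rho_1) + (B+\Delta B)\hat g(y(k-\delta(k)))
#'   + (E+\Delta E)\sum_s \mu_s h(y(k-s)) + \sigma(k, x(k-\rho_1))\omega(k)
#'   + L_x v_x(k)}
#' \deqn{y(k+1) = -(C+\Delta C)y(k-\rho_2) + (D+\Delta D)x(k-\tau(k))
#'   + (F+\Delta F)\sum_n \xi_n x(k-n) + L_y v_y(k)}
#' with measurements `Z_x = M x`, `Z_y = N y` delivered through a Bernoulli
#' dropout channel with success probabilities `alpha0`, `beta0`.
#'
#' @param A,C diagonal degradation-rate matrices (n x n, strictly positive
#'   diagonal).
#' @param D translation-rate matrix (n x n, diagonal with strictly positive
#'   diagonal).
#' @param B transcriptional coupling matrix (n x n).
#' @param E,F distributed-delay weight matrices (n x n).
#' @param H noise-intensity bound matrix: the noise term satisfies
#'   \eqn{\sigma^T\sigma \le x^T H x}; must be symmetric positive definite.
#' @param L_x,L_y disturbance input matrices (n x n).
#' @param M,N measurement matrices (l x n).
#' @param rho1,rho2 leakage delays (non-negative integers).
#' @param delta_m,delta_M bounds of the feedback-regulation delay
#'   \eqn{\delta(k)}.
#' @param tau_m,tau_M bounds of the translation delay \eqn{\tau(k)}.
#' @param mu_kernel,xi_kernel distributed-delay kernels, see
#'   [exponential_kernel()] / [finite_kernel()].
#' @param alpha0,beta0 dropout success probabilities in (0, 1].
#' @param hill per-gene Hill exponents (recycled to length n).
#' @param uncertainty optional [uncertainty_structure()].
#' @param sigma optional noise-intensity factor \eqn{\Sigma} with
#'   \eqn{\Sigma^T\Sigma \preceq H}; default is the symmetric square root
#'   \eqn{H^{1/2}} (the tight case).
#' @param extras named list of parameters stored verbatim but not consumed
#'   by the dynamics.
#' @return an object of class `grn_model`.
#' @export
grn_model <- function(A, B, C, D, E, F, H, L_x, L_y, M, N,
                      rho1 = 0L, rho2 = 0L,
                      delta_m = 0L, delta_M = 0L, tau_m = 0L, tau_M = 0L,
                      mu_kernel = exponential_kernel(2),
                      xi_kernel = exponential_kernel(2),
                      alpha0 = 1, beta0 = 1,
                      hill = 2,
                      uncertainty = NULL,
                      sigma = NULL,
                      extras = list()) {
  A <- as.matrix(A)
  n <- nrow(A)
  A <- .as_matrix(A, n, n, "A")
  B <- .as_matrix(B, n, n, "B")
  C <- .as_matrix(C, n, n, "C")
  D <- .as_matrix(D, n, n, "D")
  E <- .as_matrix(E, n, n, "E")
  F <- .as_matrix(F, n, n, "F")
  H <- .as_matrix(H, n, n, "H")
  L_x <- .as_matrix(L_x, n, n, "L_x")
  L_y <- .as_matrix(L_y, n, n, "L_y")
  M <- as.matrix(M)
  l <- nrow(M)
  M <- .as_matrix(M, l, n, "M")
  N <- .as_matrix(N, l, n, "N")

  for (nm in c("A", "C", "D")) {
    mat <- get(nm)
    if (!.is_diagonal(mat)) {
      stop(sprintf("'%s' must be diagonal", nm), call. = FALSE)
    }
    if (any(diag(mat) <= 0)) {
      stop(sprintf("diagonal entries of '%s' must be strictly positive", nm),
           call. = FALSE)
    }
  }

  H <- .sym_check(H, "H")
  if (min(eigen(H, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("'H' must be positive definite", call. = FALSE)
  }

  delays <- c(rho1 = rho1, rho2 = rho2, delta_m = delta_m,
              delta_M = delta_M, tau_m = tau_m, tau_M = tau_M)
  if (any(delays < 0) || any(delays != round(delays))) {
    stop("delays and delay bounds must be non-negative integers",
         call. = FALSE)
  }
  if (delta_m > delta_M || tau_m > tau_M) {
    stop("delay bounds must satisfy delta_m <= delta_M and tau_m <= tau_M",
         call. = FALSE)
  }

  if (!(alpha0 > 0 && alpha0 <= 1) || !(beta0 > 0 && beta0 <= 1)) {
    stop("'alpha0' and 'beta0' must lie in (0, 1]", call. = FALSE)
  }

  mu_kernel <- as_grn_kernel(mu_kernel)
  xi_kernel <- as_grn_kernel(xi_kernel)

  hill <- rep_len(as.numeric(hill), n)
  if (any(hill <= 0)) stop("Hill exponents must be positive", call. = FALSE)

  if (!is.null(uncertainty)) {
    stopifnot(inherits(uncertainty, "grn_uncertainty"))
    if (nrow(uncertainty$R) != n) {
      stop("uncertainty structure dimension does not match the model",
           call. = FALSE)
    }
  }

  if (is.null(sigma)) {
    eh <- eigen(H, symmetric = TRUE)
    sigma <- eh$vectors %*% (sqrt(pmax(eh$values, 0)) * t(eh$vectors))
  } else {
    sigma <- .as_matrix(sigma, n, n, "sigma")
    gap <- H - crossprod(sigma)
    if (min(eigen((gap + t(gap)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-9 * max(1, max(abs(H)))) {
      stop("noise factor violates the intensity bound: sigma' sigma must not exceed H",
           call. = FALSE)
    }
  }

  structure(
    list(n = n, l = l, A = A, B = B, C = C, D = D, E = E, F = F, H = H,
         L_x = L_x, L_y = L_y, M = M, N = N,
         rho1 = as.integer(rho1), rho2 = as.integer(rho2),
         delta_m = as.integer(delta_m), delta_M = as.integer(delta_M),
         tau_m = as.integer(tau_m), tau_M = as.integer(tau_M),
         mu_kernel = mu_kernel, xi_kernel = xi_kernel,
         alpha0 = alpha0, beta0 = beta0, hill = hill,
         uncertainty = uncertainty, sigma = sigma, extras = extras),
    class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat(sprintf("<grn_model> n = %d genes, l = %d outputs\n", x$n, x$l))
  cat(sprintf("  leakage rho = (%d, %d); delta in [%d, %d]; tau in [%d, %d]\n",
              x$rho1, x$rho2, x$delta_m, x$delta_M, x$tau_m, x$tau_M))
  cat(sprintf("  dropout alpha0 = %g, beta0 = %g; Hill exponents: %s\n",
              x$alpha0, x$beta0, paste(x$hill, collapse = ", ")))
  cat(sprintf("  uncertainty: %s\n",
              if (is.null(x$uncertainty)) "none" else "norm-bounded R N(k) W_i"))
  invisible(x)
}

#' Estimator gain record
#'
#' The four gain matrices of the state estimator
#' \eqn{\hat x(k+1) = -A_x \hat x(k) + B_x \tilde Z_x(k)},
#' \eqn{\hat y(k+1) = -A_y \hat y(k) + B_y \tilde Z_y(k)}.
#'
#' @param A_x,A_y state-feedback gains (n x n).
#' @param B_x,B_y output-injection gains (n x l).
#' @return an object of class `grn_gains`.
#' @export
grn_gains <- function(A_x, B_x, A_y, B_y) {
  A_x <- as.matrix(A_x)
  n <- nrow(A_x)
  B_x <- as.matrix(B_x)
  l <- ncol(B_x)
  structure(list(A_x = .as_matrix(A_x, n, n, "A_x"),
                 B_x = .as_matrix(B_x, n, l, "B_x"),
                 A_y = .as_matrix(A_y, n, n, "A_y"),
                 B_y = .as_matrix(B_y, n, l, "B_y"),
                 n = n, l = l),
            class = "grn_gains")
}

#' Zero estimator gains
#' @param n state dimension
#' @param l output dimension
#' @return `grn_gains` with all four matrices zero.
#' @export
zero_gains <- function(n, l = n) {
  z <- matrix(0, n, n)
  grn_gains(z, matrix(0, n, l), z, matrix(0, n, l))
}

#' Norm-bounded uncertainty structure
#'
#' Perturbations of the six system matrices take the factored form
#' \eqn{[\Delta A, \ldots, \Delta F](k) = R\, N(k)\, [W_1, \ldots, W_6]}
#' with a time-varying contraction \eqn{N(k)^T N(k) \le I}.
#'
#' @param R left factor (n x n).
#' @param W1,W2,W3,W4,W5,W6 right factors (n x n); a single matrix may be
#'   recycled by passing it to every slot.
#' @return an object of class `grn_uncertainty`.
#' @export
uncertainty_structure <- function(R, W1, W2 = W1, W3 = W1, W4 = W1,
                                  W5 = W1, W6 = W1) {
  R <- as.matrix(R)
  n <- nrow(R)
  out <- list(R = .as_matrix(R, n, n, "R"))
  Ws <- list(W1, W2, W3, W4, W5, W6)
  for (i in seq_len(6)) {
    out[[paste0("W", i)]] <- .as_matrix(Ws[[i]], n, n, paste0("W", i))
  }
  structure(out, class = "grn_uncertainty")
}

#' Sample admissible parameter perturbations
#'
#' Draws the six perturbation matrices \eqn{\Delta A(k), \ldots, \Delta F(k)
#' = R N(k) W_i} for one time index. Three modes are supported:
#' `"off"` (zero perturbations), `"paper-trig"` (the diagonal
#' \eqn{N(k) = \mathrm{diag}(\sin(k\pi/2), \cos(k\pi/2), \ldots)} pattern,
#' alternating sine/cosine across coordinates), and `"random-contraction"`
#' (a seeded random orthogonal matrix scaled by uniform(0,1] singular
#' values). Every mode produces \eqn{\sigma_{max}(N(k)) \le 1}.
#'
#' @param structure an [uncertainty_structure()], or `NULL` (treated as off).
#' @param k time index (non-negative integer).
#' @param mode one of `"off"`, `"paper-trig"`, `"random-contraction"`.
#' @param seed required for `"random-contraction"`; the draw is a
#'   deterministic function of (seed, k).
#' @param n state dimension, needed when `structure` is `NULL`.
#' @return list with elements `DeltaA` ... `DeltaF` and the contraction `Nk`.
#' @export
sample_uncertainty <- function(structure, k,
                               mode = c("off", "paper-trig",
                                        "random-contraction"),
                               seed = NULL, n = NULL) {
  mode <- match.arg(mode)
  if (is.null(structure)) {
    if (is.null(n)) stop("'n' needed when structure is NULL", call. = FALSE)
    z <- matrix(0, n, n)
    return(list(DeltaA = z, DeltaB = z, DeltaC = z, DeltaD = z,
                DeltaE = z, DeltaF = z, Nk = z))
  }
  n <- nrow(structure$R)
  Nk <- switch(mode,
    "off" = matrix(0, n, n),
    "paper-trig" = diag(ifelse(seq_len(n) %% 2 == 1,
                               sin(k * pi / 2), cos(k * pi / 2)),
                        nrow = n),
    "random-contraction" = {
      if (is.null(seed)) {
        stop("random-contraction mode requires a seed", call. = FALSE)
      }
      contraction_matrix(n, seed = seed, k = k)
    })
  delta <- lapply(seq_len(6), function(i) {
    structure$R %*% Nk %*% structure[[paste0("W", i)]]
  })
  names(delta) <- paste0("Delta", c("A", "B", "C", "D", "E", "F"))
  c(delta, list(Nk = Nk))
}

# Random orthogonal x uniform(0,1] scaling; deterministic in (seed, k).
contraction_matrix <- function(n, seed, k = 0L) {
  rs <- local_rng((as.numeric(seed) * 1000003 + as.numeric(k)) %% 2147483647)
  on.exit(rs())
  Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  s <- runif(n, min = .Machine$double.eps, max = 1)
  Q %*% (s * t(Q))
}

# Evaluate an RNG-consuming block under a private seed; returns a restore
# function for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed %% 2147483646L) + 1L)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Hill activation function
#'
#' The monotone transcription-regulation nonlinearity
#' \eqn{\hat g(s) = s^h / (1 + s^h)} for non-negative argument `s` and Hill
#' exponent `h > 0`. Values lie in `[0, 1)` and increase strictly in `s`.
#'
#' @param s non-negative argument (vectorized).
#' @param h Hill exponent, positive scalar.
#' @return values of \eqn{s^h/(1+s^h)}.
#' @export
hill_activation <- function(s, h = 2) {
  if (!is.numeric(s) || any(s < 0)) {
    stop("'s' must be non-negative", call. = FALSE)
  }
  if (!is.numeric(h) || length(h) != 1 || h <= 0) {
    stop("'h' must be a positive scalar", call. = FALSE)
  }
  p <- s^h
  p / (1 + p)
}

# Even extension used inside the simulator, where transient states may go
# negative: coincides with hill_activation on s >= 0 and with the printed
# form for even integer exponents.
.hill_even <- function(s, h) {
  p <- abs(s)^h
  p / (1 + p)
}

#' Sector slope bounds for the regulation nonlinearity
#'
#' Records slope matrices `N1`, `N2` for the sector condition
#' \deqn{[\hat g(x)-\hat g(y)-N_1(x-y)]^T[\hat g(x)-\hat g(y)-N_2(x-y)]
#'   \le 0,}
#' together with the derived quantities
#' \eqn{\tilde N_1 = (N_1^T N_2 + N_2^T N_1)/2} and
#' \eqn{\tilde N_2 = -(N_1^T + N_2^T)/2} used by the stability LMIs. The
#' difference `N1 - N2` must be sign-definite (the sector has nonzero
#' width); since the quadratic form is symmetric under swapping the two
#' slopes, either ordering is accepted and canonicalized internally so that
#' the stored difference is positive definite.
#'
#' @param N1,N2 slope matrices (n x n).
#' @return an object of class `grn_sector` with elements `N1`, `N2`,
#'   `Ntilde1`, `Ntilde2`, `swapped`.
#' @export
sector_bounds <- function(N1, N2) {
  N1 <- as.matrix(N1)
  n <- nrow(N1)
  N1 <- .as_matrix(N1, n, n, "N1")
  N2 <- .as_matrix(N2, n, n, "N2")
  diff <- .sym_check(N1 - N2, "N1 - N2")
  ev <- eigen(diff, symmetric = TRUE, only.values = TRUE)$values
  swapped <- FALSE
  if (all(ev > 0)) {
    # ordering already satisfies the positive-definiteness convention
  } else if (all(ev < 0)) {
    tmp <- N1; N1 <- N2; N2 <- tmp
    swapped <- TRUE
  } else {
    stop("sector width N1 - N2 must be sign-definite (and nonzero)",
         call. = FALSE)
  }
  structure(list(
    N1 = N1, N2 = N2,
    Ntilde1 = (t(N1) %*% N2 + t(N2) %*% N1) / 2,
    Ntilde2 = -(t(N1) + t(N2)) / 2,
    swapped = swapped, n = n), class = "grn_sector")
}

#' Verify a sector bound by sampling
#'
#' Evaluates the sector quadratic form for a scalar (per-coordinate)
#' activation on all pairs of grid points and reports whether it stays below
#' tolerance, along with the worst violation and where it occurred. The
#' sector condition quantifies over all pairs; sampling furnishes a
#' falsification surface, not a proof.
#'
#' @param activation scalar function applied per coordinate (e.g.
#'   `function(s) hill_activation(s, 2)`).
#' @param bounds a [sector_bounds()] object with diagonal slope matrices, or
#'   a numeric pair `c(n1, n2)` of scalar slopes.
#' @param grid numeric vector of non-negative sample points; all ordered
#'   pairs are tested.
#' @param tol absolute tolerance on the quadratic form (default `1e-9`).
#' @return list with `holds` (logical), `max_violation`, and `argmax`
#'   (the worst `(x, y)` pair).
#' @export
verify_sector <- function(activation, bounds, grid, tol = 1e-9) {
  if (length(grid) == 0) stop("'grid' must be non-empty", call. = FALSE)
  if (any(grid < 0)) {
    stop("'grid' points must be non-negative", call. = FALSE)
  }
  if (inherits(bounds, "grn_sector")) {
    if (!.is_diagonal(bounds$N1) || !.is_diagonal(bounds$N2)) {
      stop("sampled verification requires diagonal slope matrices",
           call. = FALSE)
    }
    slopes <- cbind(diag(bounds$N1), diag(bounds$N2))
  } else {
    slopes <- matrix(as.numeric(bounds), nrow = 1, ncol = 2)
  }
  g <- vapply(grid, activation, numeric(1))
  worst <- -Inf
  argmax <- c(NA_real_, NA_real_)
  for (i in seq_len(nrow(slopes))) {
    n1 <- slopes[i, 1]; n2 <- slopes[i, 2]
    dg <- outer(g, g, "-")
    dx <- outer(grid, grid, "-")
    form <- (dg - n1 * dx) * (dg - n2 * dx)
    w <- which.max(form)
    if (form[w] > worst) {
      worst <- form[w]
      argmax <- c(grid[row(form)[w]], grid[col(form)[w]])
    }
  }
  list(holds = worst <= tol, max_violation = worst, argmax = argmax)
}

#' Noise-intensity evaluation
#'
#' Applies a linear noise-intensity factor to the lagged state:
#' \eqn{\sigma(k, x) = \Sigma x}. The factor must satisfy the quadratic
#' bound \eqn{\Sigma^T \Sigma \preceq H}, which makes
#' \eqn{\sigma^T\sigma \le x^T H x} hold for every state by construction.
#'
#' @param x_lagged state vector.
#' @param Sigma intensity factor (n x n).
#' @param H noise bound matrix; when supplied the factor is validated
#'   against it.
#' @param tol eigenvalue tolerance for the validation.
#' @return the vector \eqn{\Sigma x}.
#' @export
noise_intensity <- function(x_lagged, Sigma, H = NULL, tol = 1e-9) {
  Sigma <- as.matrix(Sigma)
  if (!is.null(H)) {
    gap <- H - crossprod(Sigma)
    gap <- (gap + t(gap)) / 2
    if (min(eigen(gap, symmetric = TRUE, only.values = TRUE)$values) <
        -tol * max(1, max(abs(H)))) {
      stop("intensity factor violates the bound: Sigma' Sigma must not exceed H",
           call. = FALSE)
    }
  }
  drop(Sigma %*% x_lagged)
}
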