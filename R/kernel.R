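# Distributed-delay kernels. The dynamics sum over the infinite past with
# summable non-negative weights; simulation truncates the tail at a relative
# mass tolerance.

#' Exponential distributed-delay kernel
#'
#' The family \eqn{\mu_s = e^{-c s}}, `s = 1, 2, ...`, with decay rate
#' `c > 0`. Its total mass is the geometric sum
#' \eqn{e^{-c} / (1 - e^{-c})}.
#'
#' @param rate decay rate `c > 0`.
#' @return an object of class `grn_kernel`.
#' @export
exponential_kernel <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("'rate' must be a positive scalar", call. = FALSE)
  }
  structure(list(type = "exponential", rate = rate), class = "grn_kernel")
}

#' Finite distributed-delay kernel
#'
#' A kernel supported on `s = 1, ..., length(weights)` with the given
#' non-negative weights.
#'
#' @param weights non-negative weight vector.
#' @return an object of class `grn_kernel`.
#' @export
finite_kernel <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) < 1 || any(weights < 0) || !all(is.finite(weights))) {
    stop("'weights' must be non-negative and finite", call. = FALSE)
  }
  structure(list(type = "finite", weights = weights), class = "grn_kernel")
}

#' @rdname exponential_kernel
#' @param x object to coerce: a `grn_kernel`, a positive rate (interpreted
#'   as an exponential kernel, matching the examples' printed scalars), or a
#'   weight vector.
#' @export
as_grn_kernel <- function(x) {
  if (inherits(x, "grn_kernel")) return(x)
  if (is.numeric(x) && length(x) == 1) return(exponential_kernel(x))
  if (is.numeric(x)) return(finite_kernel(x))
  stop("cannot interpret 'x' as a distributed-delay kernel", call. = FALSE)
}

#' Total kernel mass
#' @param kernel a `grn_kernel`.
#' @return \eqn{\sum_s \mu_s} (closed form for the exponential family).
#' @export
kernel_mass <- function(kernel) {
  kernel <- as_grn_kernel(kernel)
  switch(kernel$type,
         exponential = exp(-kernel$rate) / (1 - exp(-kernel$rate)),
         finite = sum(kernel$weights))
}

#' Truncate a distributed-delay kernel
#'
#' Finds the smallest truncation length `s_max` whose discarded tail mass
#' does not exceed `rel_tol` times the total mass, and returns the retained
#' weights. For the exponential family the tail is geometric, so
#' \eqn{\sum_{s > m} e^{-cs} \le \mathrm{rel\_tol} \cdot \sum_s e^{-cs}}
#' reduces to \eqn{e^{-cm} \le \mathrm{rel\_tol}}.
#'
#' @param kernel a `grn_kernel` (or coercible).
#' @param rel_tol relative tail-mass tolerance (default `1e-12`).
#' @return list with `s_max`, `weights` (length `s_max`), `total` (full
#'   mass), and `tail` (discarded mass).
#' @export
truncate_kernel <- function(kernel, rel_tol = 1e-12) {
  kernel <- as_grn_kernel(kernel)
  if (!is.numeric(rel_tol) || rel_tol <= 0 || rel_tol >= 1) {
    stop("'rel_tol' must lie in (0, 1)", call. = FALSE)
  }
  total <- kernel_mass(kernel)
  if (!is.finite(total)) stop("kernel is not summable", call. = FALSE)
  if (kernel$type == "exponential") {
    c0 <- kernel$rate
    s_max <- max(1L, as.integer(ceiling(-log(rel_tol) / c0)))
    weights <- exp(-c0 * seq_len(s_max))
    tail <- exp(-c0 * (s_max + 1)) / (1 - exp(-c0))
  } else {
    w <- kernel$weights
    # drop the all-zero tail, then cut where cumulative tail mass falls
    # below tolerance
    cum_tail <- rev(cumsum(rev(w)))
    keep <- which(cum_tail > rel_tol * total)
    s_max <- if (length(keep)) max(keep) else 1L
    weights <- w[seq_len(s_max)]
    tail <- total - sum(weights)
  }
  list(s_max = s_max, weights = weights, total = total, tail = tail)
}
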