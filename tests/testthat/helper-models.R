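# Small models built in code for the tests.

# scalar network with all couplings (numerically) off: x(k+1) = -a x(k-rho1)
scalar_toy <- function(a = 0.5, c = 0.5, rho = 0L) {
  grn_model(A = matrix(a), B = matrix(0), C = matrix(c),
            D = matrix(1e-12), E = matrix(0), F = matrix(0),
            H = matrix(1e-4), L_x = matrix(0), L_y = matrix(0),
            M = matrix(1), N = matrix(1),
            rho1 = rho, rho2 = rho,
            delta_m = 0L, delta_M = 0L, tau_m = 0L, tau_M = 0L,
            mu_kernel = finite_kernel(1e-300), xi_kernel = finite_kernel(1e-300),
            alpha0 = 1, beta0 = 1, hill = 2)
}

const_schedule <- function(d = 0L, t = 0L) grn_schedule(d, t)

default_sector2 <- function() {
  sector_bounds(N1 = diag(0.65, 2), N2 = matrix(0, 2, 2))
}

# two-gene contraction used by the LMI tests (deterministic)
toy_model <- function(seed = 1) {
  random_stable_model(seed, n = 2, target_contraction = 0.3)
}
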