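---
title: "Robust state estimation for delayed stochastic gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust state estimation for delayed stochastic gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnest)
```

## The model

A discrete-time gene regulatory network couples mRNA concentrations
$x(k) \in \mathbb{R}^n$ and protein concentrations $y(k) \in \mathbb{R}^n$:

$$
\begin{aligned}
x(k+1) &= -(A+\Delta A(k))\,x(k-\rho_1)
          + (B+\Delta B(k))\,\hat g\!\big(y(k-\delta(k))\big)
          + (E+\Delta E(k))\sum_{s=1}^{\infty}\mu_s\,h\big(y(k-s)\big) \\
       &\quad + \sigma\big(k, x(k-\rho_1)\big)\,\omega(k) + L_x v_x(k),\\
y(k+1) &= -(C+\Delta C(k))\,y(k-\rho_2)
          + (D+\Delta D(k))\,x(k-\tau(k))
          + (F+\Delta F(k))\sum_{n=1}^{\infty}\xi_n\,x(k-n) + L_y v_y(k).
\end{aligned}
$$

$A, C$ are diagonal degradation-rate matrices and $D$ the diagonal
translation-rate matrix (all strictly positive); $B$ is the transcriptional
coupling matrix; $E, F$ weight the distributed delays. The leakage delays
$\rho_1, \rho_2$ lag the degradation feedback itself; $\delta(k), \tau(k)$
are bounded integer time-varying delays; the kernels $\mu_s, \xi_n$ are
summable non-negative sequences (default the exponential family
$\mu_s = e^{-cs}$). Regulation is Hill-type,
$\hat g(s) = s^h/(1+s^h)$, which satisfies a sector bound with slopes
$0$ and $3\sqrt{3}/8 \approx 0.6495$ for $h = 2$. Parameter uncertainty is
norm-bounded, $[\Delta A, \ldots, \Delta F](k) = R\,N(k)\,[W_1,\ldots,W_6]$
with $N(k)^\top N(k) \le I$. The multiplicative noise satisfies
$\sigma^\top \sigma \le x^\top H x$ for a known SPD bound $H$.

Measurements $Z_x = Mx$, $Z_y = Ny$ reach the estimator through a Bernoulli
dropout channel: with probability $\alpha_0$ (resp. $\beta_0$) the current
measurement arrives, otherwise the one-step-old one. The estimator is the
linear observer

$$
\hat x(k+1) = -A_x \hat x(k) + B_x \tilde Z_x(k), \qquad
\hat y(k+1) = -A_y \hat y(k) + B_y \tilde Z_y(k),
$$

and the package's purpose is to choose the four gains so that the augmented
state/error vector is mean-square exponentially stable
($\mathbb{E}\{|\bar x(k)|^2 + |\bar y(k)|^2\} \le \alpha\mu^k \cdot
\text{(initial data)}$ with $\mu < 1$) and, from zero initial conditions,
satisfies the disturbance attenuation bound
$\sum_k \mathbb{E}\{|\bar x|^2 + |\bar y|^2\} \le
\gamma^2 \sum_k (|v_x|^2 + |v_y|^2)$.

## What the simulator does

`simulate_grn()` integrates the network, the dropout channel, the observer,
and — in the same pass, from the same realized draws — the estimation-error
recursion both directly and by subtraction. The two error records must agree
to round-off (this identity is definitional, and the test suite asserts it
on dozens of seeded runs); keeping both makes any future divergence between
the model's error dynamics and its implementation immediately visible.

Numerical choices:

* **Kernel truncation.** The infinite distributed sums are truncated at a
  relative tail mass `rel_tol` (default $10^{-12}$); for the exponential
  family the truncation length solves $e^{-cm} \le \text{rel\_tol}$ in
  closed form. States before the supplied history window are zero, so the
  truncation error is bounded by the tail mass times the trajectory
  sup-norm.
* **Noise.** The model only bounds the noise intensity; the simulator's
  default factor is the tight symmetric square root $\Sigma = H^{1/2}$, and
  any user-supplied factor is validated against
  $\Sigma^\top\Sigma \preceq H$. $\omega(k)$ is i.i.d. standard normal —
  the second-moment analysis uses only $\mathbb{E}\omega = 0$,
  $\mathbb{E}\omega^2 = 1$, uncorrelatedness.
* **Delay schedules** must evaluate to integers inside the declared bounds;
  non-integer values are rejected rather than rounded (silent rounding
  could violate the bounds). An absolute integrality tolerance of $10^{-9}$
  absorbs floating-point noise in expressions like $3 + 2\sin(k\pi/2)$.
* **Negative transients.** The user-facing `hill_activation()` is defined
  on $s \ge 0$; inside the simulator, transient states can be negative, so
  the dynamics evaluate the even extension $|s|^h/(1+|s|^h)$, identical on
  the nonnegative orthant and identical to the printed form for the
  even exponents the examples use. For the same reason the sector bound
  itself only holds on the nonnegative orthant, and `verify_sector()`
  samples there.
* **RNG partition.** One master seed is split into independent streams for
  the process noise, the two dropout sequences, and uncertainty draws, so
  toggling one source does not shift the others.

## The stability and synthesis LMIs

`assemble_analysis()`, `assemble_hinf()`, `assemble_synthesis()` and
`assemble_nominal()` build the pairs of symmetric block matrices
$\Lambda_1, \Lambda_2$ whose simultaneous negative definiteness certifies,
respectively: exponential stability for given gains; stability with
attenuation level $\gamma$; the same with the gains eliminated through the
linearizing substitution $X_1 = R_{21}A_x$, $X_2 = R_{21}B_x$,
$Y_1 = R_{22}A_y$, $Y_2 = R_{22}B_y$ (so gain synthesis is jointly affine);
and the uncertainty-free corollary form. Decision variables are ten SPD
matrices $R_{11}, \ldots, R_{52}$ (the Lyapunov–Krasovskii weights), three
positive scalars $\lambda, \varepsilon_1, \varepsilon_2$ (the sector
multiplier and the uncertainty-absorption scalars), and, for synthesis, the
free matrices $X_1, X_2, Y_1, Y_2$. For $n = 2$ the matrices are
$38\times38$/$46\times46$ (analysis) and $40\times40$/$48\times48$ (with
the disturbance block).

### Two fidelity readings

As printed, the conditions contain diagonal blocks whose sign is forced by
the positive definiteness of the decision matrices: the noise-bound block
$HR_{11}$ and the distributed-state block $(R_{12}+R_{22})$ in
$\Lambda_1$; the block $(R_{11}+R_{21})$, the kernel block
$\bar\mu R_{51}$, and an identically zero diagonal block on the protein
leakage coordinate in $\Lambda_2$. A symmetric matrix with a non-negative
diagonal entry cannot be negative definite, so the printed reading is
structurally infeasible for every model. The package exposes both readings
explicitly:

* **`fidelity = "paper"`** assembles every block with its printed sign.
  `solve_lmi()` recognizes the sign-forced blocks and returns certified
  infeasibility with a diagnosis naming them, without any numerical search.
* **`fidelity = "repaired"`** is this package's interpretation of the lost
  sign convention: the four sign-forced blocks are negated (products with
  $H$ symmetrized as $(HR_{11}+R_{11}H)/2$, since a Lyapunov block must be
  symmetric), and the zero protein-leakage block is set to
  $-(R_{12}+R_{22})$, mirroring the treatment of the mRNA leakage
  coordinate. The repair is a documented interpretation, never silently
  applied.

A second, independent defect concerns the disturbance channel: in the
printed attenuation form the $-\gamma^2 I$ block is completely decoupled
(the disturbance columns of every coupling row are zero and $L_x, L_y$
appear in no block), which would make the level $\gamma$ vacuous — any
positive value would be "feasible" while saying nothing about the energy
gain. The repaired reading therefore also restores the two ingredients the
energy argument needs: $+I$ on the current-state and error coordinates (the
output energy of the attenuation definition) and the disturbance couplings
$\sqrt2(R_{11}+R_{21})L_x$, $\sqrt2 R_{21}L_x$ (and the $L_y$ analogues)
in the two dynamics rows, which is where the $Lv$ term of the state and
error updates enters the Lyapunov difference. With this reading the
minimized $\gamma$ is finite and meaningfully bounds the Monte-Carlo
energy ratio (the test suite checks this); in the printed reading the
deletion identity — removing the disturbance row and column reproduces the
analysis form entrywise — holds exactly and is tested.

The symbol $T$ in the uncertainty-absorption rows is identified with the
left factor $R$ of the uncertainty structure: the factorization
$\Delta S_1 = \bar T_1 N(k) \bar W_1$ only matches
$\Delta(\cdot) = R N(k) W_i$ under that identification.

### The solver

No semidefinite-programming backend is available to this package, and the
problems are small (at most $48 \times 48$, about 50 decision scalars) and
affine, so `solve_lmi()` implements a direct spectral method: minimize a
smoothed maximum eigenvalue (matrix log-sum-exp with an increasing
temperature schedule) of all shifted constraint matrices
($\Lambda_i + \varepsilon I \preceq 0$, $R_j \succeq \varepsilon I$,
scalars $\ge \varepsilon$) by BFGS with exact gradients from the
eigenvector weights. The objective is convex, and because every
variable-dependent term is linear in the variables, any strictly feasible
point can be rescaled to enlarge its margins — the solver uses this as a
final polish. Feasibility is always re-certified by exact eigenvalue
computation at the returned point; `status = "feasible"` means both
margins meet the strictness level. Strict inequalities use the
conventional shift $\varepsilon_{\text{strict}}$, default $10^{-7}$ scaled
by the magnitude of the assembled matrices. Gains are recovered by linear
solves with a condition-number gate ($10^8$) on $R_{21}, R_{22}$.
`minimize_gamma()` bisects on the attenuation level (warm-starting each
solve) to 5% relative resolution.

## Monte-Carlo verification

The LMI certificates are sufficient conditions under an interpretation of
a flawed printed derivation, so the package closes the loop empirically:

* `verify_exponential()` simulates ensembles from seeded random initial
  histories with zero disturbances, fits $\log \mathbb{E}\{|\bar x|^2 +
  |\bar y|^2\}$ linearly in $k$, and requires the fitted decay factor's
  upper confidence bound below 1 for every uncertainty mode in the sweep.
  The fit window opens after the delay transients
  ($\max(\tau_M,\delta_M,\rho_1,\rho_2)+1$ steps) and closes before the
  series reaches 100 machine epsilons of its peak, so the log of the
  numerical noise floor is never fitted; a fit is reported only when its
  $R^2$ exceeds 0.9.
* `verify_hinf()` simulates from zero initial conditions under a bank of
  finite-energy disturbances (default the decaying sinusoids
  $v_x(k) = \sin(6k)e^{-0.1k}$, $v_y(k) = \cos(2k)e^{-0.2k}$ shipped with
  the examples) and compares the worst ensemble energy ratio against
  $\gamma^2$.
* The default uncertainty sweep is {off, the trigonometric diagonal
  contraction, 8 seeded random orthogonal-times-uniform contractions}.
  Robustness quantifies over *all* admissible contractions; a finite sweep
  is a falsification surface, not a proof, and is documented as such.

## Packaged examples and the synthetic model generator

`grn_example()` ships the two printed two-gene parameter sets. The first
example is printed twice with conflicting values; both printings are kept
as explicit variants (`"4.1a"`, `"4.1b"`) and downstream commands require
a choice. Fields one printing omits are filled from the other (measurement
matrices, dropout probabilities) and recorded in `notes`. Choices the
printed examples leave open, made once here: the printed scalars
$\mu = \xi = e^{-2}$ (later $e^{-1}$) are read as exponential kernels
$\mu_s = e^{-2s}$ (resp. $e^{-s}$); the unprinted noise bound is
$H = 0.01\,I$; the second example gets full observation $M = N = I$ and no
dropout. The matrices $d_1, d_2, G$ printed alongside the examples are
consumed by no equation of the model; they are stored verbatim under
`extras` and left unused rather than guessed at.

`random_stable_model()` generates property-test models: diagonal
degradation rates inside the contraction target, couplings rescaled so the
delay-free nonnegative linearization (degradation rates against worst-case
regulation slopes) has spectral radius at most the target (default 0.3,
with two genes — a scale at which every certificate can be exercised in
seconds). Its noise specification separates the two roles noise plays: the
*bound* $H \sim I$ is generous, because the robustness certificates
quantify over every intensity up to $H$ and the leakage block of the
repaired LMI must dominate the degradation coupling; the *realized*
intensity driving simulations is the modest factor $\Sigma = 0.05\,I$,
well inside the bound. Dropout probabilities default to
$\alpha_0 = \beta_0 = 0.9$ (occasional one-step-old measurements), delays
vary in $[1, 3]$ with leakage delays 1.

What the generator deliberately does not emulate: non-negativity of
concentrations is not enforced (the model is linear outside the Hill
terms, and transients can cross zero); kinetic parameters are drawn for
spectral convenience, not fitted to any organism; disturbances are
deterministic test signals rather than biological variability. Passing
tests on these models therefore demonstrate correctness of the machinery
and internal consistency of the certificates — not biological fidelity of
any particular network.

## A worked run

```{r example, eval = FALSE}
toy <- random_stable_model(seed = 1, n = 2, target_contraction = 0.3)
sec <- sector_bounds(N1 = diag(0.65, 2), N2 = matrix(0, 2, 2))

mg <- minimize_gamma(toy, sec)          # bisect the attenuation level
mg$gamma                                 # 0.8125
res <- mg$result                         # feasible, margins > 0
round(res$gains$A_x, 4)

verify_exponential(toy, res$gains, runs = 200, horizon = 300, seed = 7)
# stable; worst fitted decay factor ~ 0.23 across the uncertainty sweep
verify_hinf(toy, res$gains, mg$gamma, runs = 100, horizon = 150, seed = 17)
# holds; max energy ratio ~ 0.17 vs gamma^2 ~ 0.66
```

## Known limitations

* The repaired fidelity reading is an interpretation of a derivation whose
  printed form is unsatisfiable; it is validated against the Monte-Carlo
  definitions, not against a corrected proof.
* The spectral solver is a feasibility method: it certifies the points it
  finds but cannot certify infeasibility beyond the analytic sign-forced
  diagnosis (there is no dual machinery).
* The uncertainty sweep and sector sampling are finite falsification
  surfaces; worst-case formal verification over all admissible
  contractions and all state pairs is out of scope.
* The printed feasible solution of the first example is exposed for
  inspection (`printed_solution_41()`) but not reproduced: LMI feasible
  sets are not singletons, and the printed gains are inconsistent with the
  printed recovery relation $A_x = R_{21}^{-1}X_1$ (the package's tests
  document the mismatch).
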