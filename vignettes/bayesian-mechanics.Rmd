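---
title: "Bayesian mechanics of a cortical column: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian mechanics of a cortical column: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesmech)
```

## The model

`bayesmech` simulates a single cortical column performing active inference
in continuous time. The column carries two latent variables — a perceptual
state $\mu$ and a motor state $a$ — and receives a sensory stream $s(t)$.
Its generative model consists of three maps with parameters $\theta$:
a sensory prediction $g(\mu, a)$, a prior drift $f(\mu)$ on the hidden
state, and a policy prior $\pi(a)$ on the motor state. Each channel has a
precision, written as a "neural mass" $m_z, m_w, m_\eta$ (inverse noise
variance): heavier masses encode more confident predictions.

Under the Laplace (Gaussian fixed-form) assumption, the variational free
energy at an instant reduces to a precision-weighted sum of squared
prediction errors,
$$F = \tfrac{m_z}{2}(s - g)^2 + \tfrac{m_w}{2}(\dot\mu - f)^2
    + \tfrac{m_\eta}{2}(\dot a - \pi)^2,$$
up to an additive constant $\tfrac12\ln(\sigma_z\sigma_w\sigma_\eta)$ that
we drop, since it never affects the dynamics. Treating $F$ as a Lagrangian
and passing to phase space defines conjugate momenta
$p_\mu = m_w(\dot\mu - f)$ and $p_a = m_\eta(\dot a - \pi)$ — precisely the
mass-weighted prediction errors — and the Hamiltonian
$$H = \frac{p_\mu^2}{2m_w} + \frac{p_a^2}{2m_\eta}
    + p_\mu f(\mu) + p_a \pi(a) - \frac{m_z}{2}(s - g)^2.$$
Hamilton's equations over $\Psi = (\mu, a, p_\mu, p_a)$ are the
recognition dynamics (`bm_vector_field()`): perception ($\dot\mu$), motor
inference ($\dot a$) and error propagation ($\dot p_\mu, \dot p_a$) evolve
jointly. For constant $s$, $H$ is an exact invariant of the flow — the
package leans on this both as a physical statement and as an integration
diagnostic. The action `bm_action()` accumulates $\int F\,dt$ along a
trajectory by the trapezoid rule.

All state variables and parameters may be complex; the phase space is
8-real-dimensional. A deliberate and load-bearing convention: **every
quadratic form in $F$, $H$ and every product in the linear algebra is
holomorphic** (no complex conjugation). Conjugation enters exactly once,
in the cognitive intensity $|\Psi_c|^2 = \sum_i \Psi_{c,i}\Psi_{c,i}^*$.
This convention is what makes the reference parameter set reproduce its
published resting centre; a Hermitian convention would give different
dynamics entirely.

## The linear column and its attractors

With linear maps
$g = \theta_g^{(0)} + \theta_g^{(1)}\mu + \theta_g^{(2)}a$,
$f = \theta_f^{(0)} + \theta_f^{(1)}\mu$,
$\pi = \theta_\pi^{(0)} + \theta_\pi^{(2)}a$, the flow closes into
$\dot\Psi + R\Psi = I(t)$ with a 4×4 complex relaxation matrix $R$
(`relaxation_matrix()`) and a source $I$ carrying the prior intercepts and
the stimulus (`source_vector()`). Two algebraic invariants hold for *every*
parameter draw and anchor the property tests: $\mathrm{tr}\,R = 0$ (so the
eigenvalues sum to zero) and a closed-form determinant fixing their
product.

The attractor centre is the fixed point $\Psi_c = R^{-1}I(s)$. The
dynamics about it decompose over the eigenmodes
$\Psi(t) = \bar\Psi_c + \sum_\alpha c_\alpha e^{-\lambda_\alpha t}
\phi_\alpha$ (`modal_expansion()`). Whether the spectrum is exactly
pure-imaginary for a given parameter set is reported as a diagnostic
(`centre_like` in `eigen_spectrum()`), never asserted: parameter sets with
stationary (centre-like) spectra are found numerically, and classification
with threshold $|\mathrm{Re}\,\lambda| < 10^{-6}\|R\|$ is a label, not a
theorem.

### Reference parameter set

`canonical_linear_params()` is the worked-example configuration used by the
built-in experiments and tests:
intercepts $(\theta_g^{(0)}, \theta_f^{(0)}, \theta_\pi^{(0)}) = (0, 10, 10)$,
gains $\theta_g^{(1)} = 2e^{i\pi/2}$, $\theta_f^{(1)} = -1$,
$\theta_g^{(2)} = \theta_\pi^{(2)} = e^{i\pi/2}$, unit masses. All units are
arbitrary; no unit system is enforced. This set has a pure-imaginary
spectrum (frequencies $\approx 0.662$ and $2.136$), a spontaneous centre
with real projection $(-10, 10, -20)$ and cognitive intensity 1150, and a
determinant of exactly 2 — quantities the test suite recomputes rather
than trusts.

```{r}
params <- canonical_linear_params()
attractor_centre(params, s = 0)
eigen_spectrum(params)
```

## Stimuli

`stimulus_null()`, `stimulus_constant()`, `stimulus_sigmoid()` and
`stimulus_series()` cover the experiment vocabulary. The sigmoid
$s(t) = s_\infty / (1 + e^{-k(t - t_m)})$ uses saturation
$s_\infty = 100$, stiffness $k = 0.2$ and midpoint $t_m = 250$ in the
built-in active-inference experiment. For $k(t - t_m) < -700$ the sigmoid
returns exactly 0 — a representable-range convention, documented rather
than hidden. Stimuli are complex-capable for generality, though the
built-in experiments drive with real values. Series stimuli interpolate
linearly and hold endpoint values, or refuse extrapolation on request.

## Propagation and integration

Two engines solve the dynamics, and each certifies the other:

* **`propagate()`** (linear models only) is exact. For null/constant
  stimuli it evaluates $\Psi(t) = \Psi_c + e^{-Rt}(\Psi(0) - \Psi_c)$
  spectrally. For time-varying stimuli it treats the source as piecewise
  linear on each step and convolves with the one-step matrix exponential
  using $\varphi$-functions computed by the Van Loan augmented-matrix
  trick — exact for constant and linear-in-$t$ sources, so the closed-form
  limits are recovered without special-casing. Base R's `det()` and the
  `Matrix` package's `expm()` are real-only, so the package carries its own
  complex LU determinant and scaling-and-squaring Padé exponential
  (`complex_det()`, `complex_expm()`).
* **`integrate_bm()`** is a classical fixed-step 4th-order Runge–Kutta
  scheme over the generic vector field, the only engine available to
  nonlinear models. No adaptive stepping: reproducibility of the
  experiment scripts takes precedence, and correctness is certified
  against the exact propagator, not assumed from the scheme.

Numerical conventions worth stating:

* Default step $dt = 0.01$ against spectra with $|\lambda| \approx 2$:
  the local truncation $|\lambda\,dt|^5/120$ per step accumulates to a
  *relative* sup-norm error of order $10^{-7}$ over a 500-unit horizon.
  Because the data are in arbitrary units, cross-method agreement is
  always measured relative to the trajectory scale
  $\sup_t\|\Psi(t)\|$; an absolute tolerance would be meaningless under
  rescaling of the (arbitrary) units.
* Hamiltonian drift under constant input is the accuracy meter: it scales
  as $O(dt^4)$ and stays below $10^{-6}|H(0)|$ at the default step over
  the full 500-unit horizon.
* `convergence_report()` estimates the empirical order from a ladder of
  at least three steps and flags anything below 3.5.
* Models must supply analytic derivatives; a central finite-difference
  fallback (default holomorphic step $10^{-6}$) exists for user-defined
  nonlinear models and announces itself via a message and the model's
  `fd_fallback` field.
* Degenerate inputs fail loudly: singular $R$ names its determinant,
  divergence names the first bad step, an ill-conditioned eigenbasis
  (condition number above $10^8$) refuses modal expansion and points to
  `propagate()`.

## Built-in experiments

Four experiment drivers tie the pieces together, each a pure function of
its arguments:

1. **`run_spontaneous()`** — no stimulus, $\Psi(0) = 0$: the resting orbit
   about $\Psi_c(0)$.
2. **`run_static()`** and **`intensity_sweep()`** — constant stimulus:
   shifted centre $\Psi_c(s)$ and the intensity curve $|\Psi_c(s)|^2$ for
   unit masses $(1,1,1)$ versus precise masses $(10,1,10)$. The ordering
   (precision damps intensity) is asserted as an ordering, not as numeric
   targets.
3. **`run_sigmoid()`** — the saturating stimulus, integrated with RK4 so
   the run doubles as an integration test; the motor-momentum trace is the
   inference readout.
4. **`run_bifurcation()`** — the transition between the spontaneous and
   stimulus-locked attractors, reported through time-windowed means and
   bounding boxes at the snapshot times $t \in \{5, 100, 260, 500\}$.

Two design choices in the bifurcation experiment were genuinely open:

* **Initial-state completion.** The published description of this
  experiment pins only the real triple $(-16.9, 21.1, -13.3)$ of an
  8-real-dimensional state "selected from the spontaneous attractor".
  `spontaneous_state_near()` scans the spontaneous orbit for the sample
  closest to the triple in $(\mathrm{Re}\,\mu, \mathrm{Re}\,a,
  \mathrm{Re}\,p_\mu)$ and uses that *full complex* state, reporting the
  achieved distance (0.008 here, at orbit time 100). This honours the
  stated provenance without inventing the five unconstrained components.
* **Relaxation time.** With a pure-imaginary spectrum the orbit *radius*
  never decays, so "arrival" at the new attractor is defined on the
  trailing time-average of the state (default window 10 time units, about
  one slow period), which washes the oscillation out: the relaxation time
  is the first moment this running mean enters — and never again leaves —
  a ball around $\bar\Psi_c(s_\infty)$ of radius 5% of the centre shift.
  Both knobs are exposed.

## The thermodynamic layer

The package's stochastic layer verifies the nonequilibrium foundations the
deterministic theory stands on.

* **Langevin ensembles.** `simulate_paths()` integrates the over-damped
  equation $d\mu/dt = f + w$, $\langle w w'\rangle = I\delta$, by
  Euler–Maruyama, with $I = 2k_BT/(m\gamma)$ enforced as a
  fluctuation–dissipation consistency check whenever the physical
  parameters are all specified ($k_B = 1$ and arbitrary units by default).
  Initial states are drawn from the protocol's start-point equilibrium —
  required for the Jarzynski identity to hold at all. Ensembles are
  bit-reproducible under a fixed seed.
* **Work convention.** The literature leaves path-wise work definition to
  the practitioner; the package adopts the Sekimoto convention
  ($W = \sum_k V(\mu_k, \lambda_{k+1}) - V(\mu_k, \lambda_k)$, energy
  change under parameter updates at fixed state), the standard choice in
  the fluctuation-theorem literature. Two protocols ship with analytic
  $\Delta F$: the dragged harmonic trap ($\Delta F = 0$) and the stiffness
  switch ($\Delta F = \ln(\kappa_f/\kappa_i)/(2\beta)$), so the estimator
  checks are self-contained.
* **Estimators.** `jarzynski_estimate()` and `entropy_ft_estimate()`
  report $\langle e^{-\beta(W - \Delta F)}\rangle$ and
  $\langle e^{-\Delta S_{tot}/k_B}\rangle$ with Monte-Carlo standard
  errors, using max-shifted exponentials so dissipative ensembles cannot
  overflow, plus the second-law quantities
  $\langle W\rangle - \Delta F \ge 0$ and
  $\langle\Delta S_{tot}\rangle \ge 0$. Under isothermal driving
  $\Delta S_{tot}/k_B = \beta(W - \Delta F)$ path by path, which is how
  the entropy estimator derives its samples.
* **Coloured noise.** `colored_noise_check()` generates an
  Ornstein–Uhlenbeck process with stationary kernel
  $2k_BT\,\gamma\tau^{-1}e^{-|\Delta t|/\tau}$ and compares empirical
  against theoretical autocovariance (zero-lag variance, $e^{-1}$ decay at
  lag $\tau$, white-noise recovery as $\tau \to 0$).
* **Fokker–Planck diagnostics.** `fp_equilibrium_density()` normalises the
  Boltzmann density on a grid; `flux_field()` computes
  $j = pf - D\nabla p$ and $\nabla\cdot j$ by central differences. At
  equilibrium (gradient drift matched to the density) the flux is zero up
  to a second-order discretisation floor — detailed balance; adding a
  rotational drift produces a macroscopic, divergence-free flux — the
  broken-detailed-balance signature of a living (open) steady state. Only
  steady-state diagnostics are computed; transient density evolution is
  out of scope, as nothing quantitative depends on it.

## What the built-in conditions do and do not show

The reference parameter set, stimulus schedule and trap protocols *are*
the study conditions of the worked examples; they are defaults, not tuned
quantities. The simulations are noiseless in the deterministic layer (the
theory is deterministic given $s$) and Gaussian-driven in the stochastic
layer. Passing tests therefore demonstrate internal consistency of the
mechanics — exact linear algebra, certified integration, estimator
correctness at known $\Delta F$ — on a single-column, scalar-state model.
They say nothing about multi-column networks, learning of $\theta$
(explicitly out of scope), real neural data, or non-Gaussian noise.

Problem sizes used by the test suite and the acceptance script: horizons
up to 500 time units at steps between 0.01 and 0.05; eigen-analysis
property tests over 300–1000 random complex parameter draws; $10^4$
Langevin paths of $10^3$ steps for the fluctuation theorems; flux grids up
to $201$ points per dimension. These sizes are the package's own choice of
demonstration scale and are configurable at every entry point.

## Known limitations

* The symplectic structure is exploited analytically but not preserved
  numerically: RK4 is weakly dissipative on centre spectra. The exact
  propagator exists precisely to bound that error; a structure-preserving
  integrator would be attractive but has no external reference to validate
  against here.
* `modal_expansion()` requires a diagonalisable $R$; defective matrices
  (measured by eigenbasis condition number) fall back to `propagate()`.
* The interpretation of complex-valued $F$ and $H$ is left to the caller:
  both components are stored, neither is privileged.
* The stiffness-switch $\Delta F$ depends on $\beta$, so it is supplied by
  `delta_F_stiffness()` rather than stored in the protocol object — a
  deliberate guard against silently stale values.
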