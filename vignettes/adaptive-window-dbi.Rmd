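---
title: "Adaptive time-window selection for dynamical Bayesian inference of coupled oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive time-window selection for dynamical Bayesian inference of coupled oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two weakly interacting self-sustained oscillators — the canonical example
at these scales being respiration (~0.3 Hz) and the heartbeat (~1.1 Hz) —
are well described by their phase dynamics,

$$\dot\phi_i = \omega_i + q_i(\phi_i, \phi_j) + \xi_i(t), \qquad i \in \{1, 2\},$$

where $q_i$ is the coupling function describing how the partner's phase
modulates oscillator $i$'s instantaneous frequency and $\xi_i$ is white
Gaussian noise. In living systems $\omega_i$ and $q_i$ drift on timescales
of tens to hundreds of seconds. Dynamical Bayesian inference (DBI)
estimates the model from sampled phases block by block: the record is cut
into windows of length $t_w$, each window yields a posterior over the
model parameters, and that posterior — widened by a diffusion term —
becomes the prior of the next window.

Two free parameters govern the whole procedure and have traditionally
been set by hand:

* the **time window** $t_w$, which trades statistical power within a
  block against time resolution across blocks, and
* the **propagation parameter** $p_w$, the fraction of each parameter
  used as the standard deviation of its between-block diffusion,
  $\sigma_i = p_w c_i$, which encodes how much parameter change the
  method is prepared to follow.

This package implements a data-driven, two-pass selection of both, the
sequential inference itself, stochastic simulators of two reference
systems with known time-varying parameters, phase extraction from raw
signals, and post-inference coupling-function analysis.

## The inference engine

The phase velocities are modelled on a shared Fourier basis up to order
$K = 2$: a constant (whose coefficient is the natural frequency) plus
$\sin$/$\cos$ of every combination angle $k\phi_1 + s\phi_2$ with
$|k|, |s| \le K$, 25 base functions per oscillator and 50 parameters in
total (`fourier_model()`). Within a block, `infer_block()` iterates the
standard stationary-point recursion: the diagonal noise matrix is
re-estimated from the residuals of the finite-difference phase velocities
(evaluated against the basis at interval midpoints), the parameter mean
solves the concentration-weighted normal equations including the prior
term and the Jacobian drift correction, and the concentration matrix is
the prior concentration plus the data term. Iteration stops when the
parameter vector changes by less than $10^{-6}$ (relative), or after 100
iterations. With a flat prior and vanishing noise the update reduces
exactly to least squares of the finite-difference velocities on the basis;
the test suite asserts this equivalence to $10^{-8}$ against an
independent `lm.fit()` oracle.

Between blocks, `propagate_prior()` carries the mean forward and widens
the covariance by the diagonal diffusion matrix
$\Sigma_{diff} = \mathrm{diag}((p_w c_i)^2)$; parameter changes are
treated as uncorrelated. The quality of a run is summarized by the
quadrature covariance $Q_\Sigma = \sum_{ij} \Sigma_{ij}^2$, block-averaged
with the first two blocks excluded (they reflect the arbitrary flat
initial prior).

Noise cross-correlations are fixed at zero and networks of more than two
oscillators are out of scope.

## Test systems and study conditions

`simulate_phase_pair()` integrates (Euler–Maruyama, at the sampling step
$h = 0.01$ s)

$$\dot\phi_1 = \omega_1(t) + a_1\sin\phi_1 + a_3(t)\sin\phi_2 + E_{11}\xi_1,
\qquad
\dot\phi_2 = \omega_2 + a_2\sin\phi_1 + a_4\sin\phi_2 + E_{22}\xi_2,$$

with $\omega_1(t) = \omega_{1,const} - 0.5\sin(2\pi f_1 t)$ and
$a_3(t) = a_{3,const} - 0.3\sin(2\pi f_3 t + \pi/2)$. The defaults fix
the study conditions used throughout the tests: $a_1 = 0.8$, $a_2 = 0$,
$a_4 = 0.6$, $a_{3,const} = 0.8$, records of 2000 s. Where the source
ranges leave a choice we fixed, once: $\omega_{1,const} = 2\pi\,0.3$ and
$\omega_2 = 2\pi\,1.1$ rad/s (respiration- and heart-like rates),
$f_1 = f_3 = 0.005$ Hz (slow physiological variability, 200 s period),
and noise amplitudes $E_{11} = E_{22} = 0.3$, the geometric middle of the
range explored in the source study — strong enough that noise separation
is a real task, weak enough that the oscillations stay coherent. The true
$\omega_1(t)$ and $a_3(t)$ are stored with the trajectory so the
inference error $\Delta c_i$ is computable exactly (`validation_mse()`).

`simulate_poincare_pair()` provides the second reference system, two
diffusively coupled limit-cycle (Poincaré) oscillators with
$\omega_2 = 4.91$, $\varepsilon_1 = 0.05$,
$\omega_1(t) = 1 - 0.4\sin(2\pi f_1 t)$ and
$\varepsilon_2(t) = 0.2 - 0.1\sin(2\pi f_2 t)$; protophases are the
planar angles. Note a property of the explicit integrator: the stationary
cycle radius exceeds 1 by about $h\omega^2/2$ (about 5 % for the faster
oscillator at $h = 0.01$); this bias vanishes with the step size and does
not affect the phases' mean growth, but it is the reason the unit-circle
test runs at $h = 10^{-3}$.

`aperiodic_driver()` integrates the Lorenz system at the classic chaotic
parameters $(\sigma, \rho, \beta) = (10, 28, 8/3)$ — the source names no
parameter set, so the classic one is recorded in the output's `config`
attribute — compresses its time axis (0.05 Lorenz units per second) and
rescales $z(t)$ affinely into a target frequency band. `make_fixture()`
assembles respiration-like/heart-like signal pairs whose instantaneous
frequency follows a constant-plus-drift law, the sine law
$f = 0.3 + 0.2\sin(2\pi t/560)$ Hz, or the Lorenz driver; the heart-like
channel's phase velocity is weakly modulated by the respiration phase.
These fixtures emulate the *rhythm* structure of cardiorespiratory
recordings, not waveform morphology (no QRS complexes, no measurement
artifacts, no non-stationary amplitude); passing the pipeline on them
demonstrates the phase-processing chain, not robustness to raw clinical
signals.

## Phase extraction

For raw signals, `extract_phases()` chains: a linear-phase FIR band-pass
applied forward and backward (`signal::fir1` + `signal::filtfilt`), with
the order set to about three periods of the low band edge (recorded on
the result); the analytic-signal protophase; and the protophase-to-phase
transformation
$\phi = \theta + \sum_{n\ge1} 2\,\mathrm{Re}[S_n(e^{in\theta}-1)/(in)]$
with $S_n = \langle e^{-in\theta}\rangle$, 10 Fourier terms by default
and terms below the sampling noise floor $2/\sqrt{N}$ dropped. An edge
margin of three filter lengths is discarded before inference. The default
bands follow the physiological convention: 0.145–0.6 Hz for respiration,
0.6–2 Hz for the ECG-derived cardiac signal. The numerically simulated
test systems provide phases directly and are not passed through the
transformation.

## The two-pass algorithm

`optimize_inference()` implements the selection procedure end to end:

1. **Exploratory pass.** Run the sequential inference with $p_w = 0.2$
   at the smallest usable window — found by `smallest_feasible_window()`,
   which scans upward from the information floor of four velocity samples
   per base function until the run completes without a singular
   concentration matrix. This pass has the best time resolution and the
   noisiest parameters.
2. **Spectral analysis.** `estimate_fmax()` Fourier-transforms each
   inferred parameter's block series and returns the highest frequency at
   which any parameter shows a significant line, $f_{max}$.
3. **Selection.** The fastest variation needs eight blocks per period to
   be resolved, so $t_{w,opt} = T_{min}/8 = 1/(8 f_{max})$
   (`optimal_window()`), and the propagation parameter follows the
   piecewise rule (`optimal_propagation()`)
   $$p_{w,opt} = \begin{cases} 0.1 & t_{w,opt} > 40\ \mathrm{s} \\
   0.2 & t_{w,opt} \in [10, 40]\ \mathrm{s} \\
   2/t_{w,opt} & t_{w,opt} < 10\ \mathrm{s}. \end{cases}$$
4. **Optimized pass.** Re-run at $(t_{w,opt}, p_{w,opt})$; the posterior
   covariance tightens by orders of magnitude relative to pass 1.

### Automatic line detection

The source procedure determines $f_{max}$ "by observing" the parameter
dynamics and their transforms — human judgment. An artifact needs an
automatic rule, and a naive threshold (a fixed multiple of the median
spectral amplitude) fails in two characteristic ways: leakage skirts of
strong off-bin lines masquerade as high frequencies, and the stochastic
wander that the diffusion prior imprints on every estimate produces a
smooth low-frequency-heavy noise spectrum whose largest bins pass any
global threshold. The rule implemented in `estimate_fmax()` is therefore:

* block series are winsorized at median ± 5 MAD (ill-conditioned blocks
  near the feasibility floor produce outlying estimates) and
  Hann-tapered (leakage control);
* a parameter enters the search only if its series variance exceeds 1.5×
  its mean posterior variance — a calibrated estimate of a *constant*
  parameter has series variance close to its posterior variance (ratios
  measured on stationary simulations stay below ~1.1, while genuinely
  modulated parameters reach 1.9–3.7);
* a line must exceed 5× the local spectral background (median over the
  ±10 neighbouring bins, with a ±1 guard band), not a global statistic —
  no bin of a smooth noise spectrum stands far above its neighbours;
* lines below bin 5 are not considered: fewer than about five observed
  periods of a variation cannot be told apart from slow estimate drift,
  which is a statement about the required record length (records should
  span ≥ 5 periods of the slowest variability of interest);
* lines below 10 % of the strongest detected line are discarded; they
  contribute negligibly to the parameter dynamics.

When nothing passes, the error message says so: the dynamics are
indistinguishable from stationary, and any fixed window is then adequate.
On the study system the estimate lands within one block-rate bin of the
true 0.005 Hz, giving $t_{w,opt} \approx 25$ s and $p_{w,opt} = 0.2$; on
the sine-breathing fixture (560 s period) a 3000 s record yields
$t_{w,opt} \approx 59$ s and $p_{w,opt} = 0.1$.

## Coupling analysis

From each block's parameters, the cross terms — base functions depending
on the partner oscillator's phase; the constant and self terms are
excluded — define the coupling function $q_i$, evaluated on a wrapped
$2\pi \times 2\pi$ grid by `coupling_surface()` (default 100×100, figures
only; all statistics use the parameter vectors). `coupling_strength()` is
the Euclidean norm of the cross-term subvector; `similarity_index()` is
the Pearson correlation of two such subvectors, invariant to positive
rescaling — strength and shape are deliberately separate dimensions.
`time_resolved_similarity()` reports, per block and per direction, the
strength and the similarity against the block-mean coupling vector (the
basis expansion is linear, so the mean parameter vector represents the
time-averaged coupling function). Both directions are always reported;
on the phase-oscillator study system the modulated coupling $a_3(t)$ acts
on oscillator 1, so it appears in `cpl1`.

## Numerical choices

* Integrator: Euler–Maruyama at the stated $h$; the deterministic
  accuracy oracle in the tests is a tolerance-controlled Runge–Kutta
  integration (`deSolve::ode`, `ode45`) of the same vector field.
* Phases are stored unwrapped; wrapping happens only at evaluation sites.
* Windows are snapped to whole numbers of samples; `t_w_max` of a
  quadrature surface is located on the evaluation grid, without
  interpolation.
* Blocks are consecutive and non-overlapping, sharing one boundary
  sample (velocities are midpoint quantities).
* The first block's prior is flat: zero mean, zero concentration.
* A noise floor of $10^{-14}$ on the estimated noise intensities keeps
  the concentration matrix finite when a block fits perfectly
  (noise-free unit tests); it is unreachable in any realistic fit.
* `similarity_index()` errors on zero-variance vectors rather than
  returning `NaN`.

## What the diagnostics show here — and what they do not

Two empirical regularities reported for this procedure deserve comment,
because this implementation reproduces one of them only partially.

**The delayed-inference regime exists, but its onset is at smaller
$p_w$ than the nominal boundary.** When the diffusion injected between
blocks is too small, the inferred parameters cannot reach the amplitude
of the true variation: at $t_w = 2.5$ s the inferred $\omega_1(t)$
modulation amplitude falls from the true 0.5 to 0.40 at $p_w = 0.01$,
0.27 at $p_w = 0.005$, and 0.13 at $p_w = 0.002$, while the two-pass
optimum recovers ≥ 96 % of the (block-averaged) amplitude. The nominal
boundary $t_w < 1/p_w$, however, does not mark the onset here: at
$p_w = 0.2$ and $t_w = 2.5$ s (well inside the nominal delayed region)
the amplitude is fully recovered. A steady-state analysis of the
recursion explains why: with a per-window diffusion standard deviation
$\sigma_i = p_w c_i$ that does not scale with $t_w$, the tracking gain
per unit time *grows* as the window shrinks, so short windows track
better, not worse, until the singularity floor is reached.

**The quadrature covariance is monotone in $t_w$ beyond the feasibility
floor.** For the same structural reason, the block-mean $Q_\Sigma(t_w)$
at fixed $p_w$ decreases monotonically over the whole feasible range
(posterior scale $\propto t_w^{-1/2}$ in the diffusion-dominated regime,
$\propto t_w^{-1}$ in the data-dominated one), with a sharp blow-up at
the smallest usable windows where ill-conditioned blocks appear. The
maximizing window on any grid is therefore the feasibility floor
(~2 s under the study conditions), for every $p_w$; the product
$p_w \cdot t_{w,max}$ evaluates to ~0.4 at $p_w = 0.2$ and ~1.0 at
$p_w = 0.5$ rather than ~1 for both. Diffusion laws whose standard
deviation scales with the window length do produce an interior maximum
with the correct ordering in $p_w$, but they contradict the stated
per-window diffusion identity, which this package keeps. The
corresponding acceptance check is left failing rather than adjusted,
and the monotone decay beyond the maximum — which is reproduced — is
asserted separately.

Neither caveat affects the selection algorithm itself: the chosen
$(t_{w,opt}, p_{w,opt})$ lie far from both the singularity floor and the
delayed regime ($p_{w,opt} > 1/t_{w,opt}$ on every branch of the rule),
and the optimized pass tightens the covariance by two to three orders of
magnitude on the study system.

## Problem sizes used by the tests

The test suite regenerates everything from code: 2000 s study records
(200 001 samples) shared across test files, 400–1000 s records for
stationarity and recovery checks, 3000 s fixtures for the end-to-end
pipeline, and window sweeps over 2–16 s grids. The full suite runs in
about a minute on a single core; the acceptance script, which re-runs the
window sweep from scratch, takes a few minutes.

## Known limitations

* Fourier order $K = 2$ limits strongly non-linear coupling functions and
  very slow trends, as inherent to the finite basis.
* The noise matrix is diagonal (no correlated noise inference) and there
  is no network extension beyond two oscillators.
* Records must span at least ~5 periods of the slowest variability of
  interest for the spectral detection to resolve it from estimate drift;
  "time-variability of the time-variability" (recursive application) is
  not implemented.
* Fixtures are smooth oscillations; ECG morphology, artifacts and
  amplitude non-stationarity are out of scope, so real recordings need
  the usual upstream quality control before the band-pass/Hilbert chain.
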