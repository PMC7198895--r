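# dbiwin — adaptive time-window selection for dynamical Bayesian inference

When time-series of two interacting oscillators — respiration and the
heartbeat being the motivating pair — are analysed through consecutive
windows, the window length `t_w` silently decides everything: long windows
average away the time-variability one is trying to measure, short windows
drown it in estimation noise. Sequential dynamical Bayesian inference
(DBI) adds a second hidden dial, the propagation parameter `p_w`, which
sets how much of each inferred parameter `c_i` is used as the standard
deviation of its between-block diffusion (`sigma_i = p_w * c_i`) when the
posterior of one block becomes the prior of the next. Both have
traditionally been chosen by expert intuition.

`dbiwin` determines both from the data. The phase dynamics

    dphi_i/dt = omega_i + q_i(phi_i, phi_j) + xi_i(t)

are expanded on a Fourier basis up to order `K = 2` (50 parameters for a
pair), inferred block by block with diffusion propagation of the
covariance, and summarized per run by the quadrature covariance
`Q_Sigma = sum_ij Sigma_ij^2`. A two-pass procedure then fixes the dials:
an exploratory pass at the smallest usable window locates the highest
frequency `f_max` at which any model parameter genuinely varies; the
optimal window allots eight blocks to that fastest period,

    t_w_opt = 1 / (8 * f_max),

and the propagation parameter follows a piecewise rule calibrated for
cardiorespiratory-scale dynamics (`0.1` above 40 s, `0.2` in 10–40 s,
`2/t_w_opt` below 10 s). A second pass at the selected settings delivers
the final parameter tracks, from which coupling functions on the
`2*pi x 2*pi` phase grid, coupling strengths `CPL_i(t)` (norms of the
cross-term parameters) and the similarity index `rho(t)` (correlation of
coupling shapes, amplitude-invariant) are computed.

The package also ships the validation apparatus: stochastic simulators of
coupled phase oscillators and coupled Poincaré limit-cycle oscillators
with known time-varying parameters, a Lorenz-driven aperiodic frequency
driver, raw-signal fixture generation, and phase extraction (zero-phase
FIR band-pass, Hilbert protophase, protophase-to-phase transformation).

## Worked example

```r
library(dbiwin)

cfg <- phase_pair_config(seed = 42)   # the coupled-phase-oscillator study system
ps  <- simulate_phase_pair(cfg)
ps
#> phase_pair_series: 200001 samples, h = 0.01 s, duration 2000 s
#>   mean phase velocities: 1.654 and 6.885 rad/s

opt <- optimize_inference(ps)         # the full two-pass procedure
opt$plan
#> window_plan
#>   f_max    : 0.005518 Hz  (T_min = 181.2 s)
#>   t_w_opt  : 22.65 s
#>   p_w_opt  : 0.2
#>   first pass used t_w = 2.44 s
```

The generator modulates `omega_1(t)` and the coupling `a_3(t)` at
0.005 Hz; the exploratory pass recovers that frequency to within one
spectral bin, allots eight blocks per period (22.7 s windows), and picks
`p_w = 0.2` from the middle branch of the selection rule. The optimized
pass is dramatically tighter than the exploratory one:

```r
mean_qsigma(opt$initial_run)   # 0.008016
mean_qsigma(opt$run)           # 0.0001813

tr <- time_resolved_similarity(opt$run)
head(tr[, c("time", "cpl1", "rho1")], 4)
#>   time  cpl1  rho1
#> 1 11.3 0.596 0.751
#> 2 34.0 0.604 0.858
#> 3 56.6 0.842 0.973
#> 4 79.3 0.891 0.970
```

`cpl1` tracks the modulated coupling amplitude `a_3(t)` (0.5–1.1 over its
cycle) and `rho1` shows the coupling shape stabilizing after the first
blocks. Individual parameters are read off the run via the basis map,
e.g. the partner oscillator's frequency:

```r
m <- fourier_model(2)
mean(coef_matrix(opt$run)[-(1:2), basis_index(m, 2, 0, 0, "const")])
#> 6.912   (true value 6.912 rad/s)
```

For raw signals rather than phases, `extract_phases()` (band-pass +
Hilbert + protophase-to-phase) produces the input, and `pipeline()` wires
simulate → extract → optimize → couplings into one reproducible run with
all artifacts on disk; `inst/cli/dbiwin.R` exposes the same steps as a
command-line tool.

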