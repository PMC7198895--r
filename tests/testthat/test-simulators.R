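test_that("noise-free uncoupled oscillators accumulate phase linearly", {
  cfg <- phase_pair_config(a1 = 0, a2 = 0, a3_const = 0, a4 = 0,
                           omega1_mod = 0, a3_mod = 0,
                           E11 = 0, E22 = 0, duration = 50, seed = 1)
  ps <- simulate_phase_pair(cfg)
  expect_equal(ps$phi1, cfg$omega1_const * ps$time, tolerance = 1e-10)
  expect_equal(ps$phi2, cfg$omega2 * ps$time, tolerance = 1e-10)
})

test_that("noise-free trajectory matches a high-order reference integration", {
  cfg <- phase_pair_config(E11 = 0, E22 = 0, h = 0.001, duration = 20,
                           seed = 1)
  ps <- simulate_phase_pair(cfg)
  rhs <- function(t, y, p) {
    w1 <- cfg$omega1_const - cfg$omega1_mod * sin(2 * pi * cfg$f1 * t)
    a3 <- cfg$a3_const - cfg$a3_mod * sin(2 * pi * cfg$f3 * t + pi / 2)
    list(c(w1 + cfg$a1 * sin(y[1]) + a3 * sin(y[2]),
           cfg$omega2 + cfg$a2 * sin(y[1]) + cfg$a4 * sin(y[2])))
  }
  ref <- deSolve::ode(c(0, 0), ps$time, rhs, NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-10)
  # Euler global error is O(h); 2e-3 rad bounds it comfortably at h = 1 ms
  expect_lt(max(abs(ps$phi1 - ref[, 2])), 2e-3)
  expect_lt(max(abs(ps$phi2 - ref[, 3])), 2e-3)
})

test_that("simulations are reproducible from the seed", {
  a <- simulate_phase_pair(phase_pair_config(duration = 20, seed = 5))
  b <- simulate_phase_pair(phase_pair_config(duration = 20, seed = 5))
  d <- simulate_phase_pair(phase_pair_config(duration = 20, seed = 6))
  expect_identical(a$phi1, b$phi1)
  expect_identical(a$phi2, b$phi2)
  expect_false(identical(a$phi1, d$phi1))
})

test_that("doubling the noise amplitude quadruples the increment variance", {
  base <- function(E, seed) {
    cfg <- phase_pair_config(a1 = 0, a3_const = 0, a3_mod = 0,
                             omega1_mod = 0, E11 = E, E22 = 0,
                             duration = 500, seed = seed)
    ps <- simulate_phase_pair(cfg)
    stats::var(diff(ps$phi1) - cfg$omega1_const * cfg$h)
  }
  ratio <- base(0.6, 11) / base(0.3, 11)
  expect_equal(ratio, 4, tolerance = 0.05)
})

test_that("with no coupling, oscillator 2 is unaffected by oscillator 1's parameters", {
  a <- simulate_phase_pair(phase_pair_config(a2 = 0, duration = 30, seed = 3))
  b <- simulate_phase_pair(phase_pair_config(a2 = 0, omega1_const = 4,
                                             a1 = 0.1, duration = 30, seed = 3))
  expect_identical(a$phi2, b$phi2)
})

test_that("ground truth follows the stated modulation laws", {
  cfg <- phase_pair_config(duration = 10, seed = 1)
  ps <- simulate_phase_pair(cfg)
  expect_equal(ps$ground_truth$omega1,
               cfg$omega1_const - 0.5 * sin(2 * pi * cfg$f1 * ps$time))
  expect_equal(ps$ground_truth$a3,
               cfg$a3_const - 0.3 * sin(2 * pi * cfg$f3 * ps$time + pi / 2))
  expect_equal(nrow(ps$ground_truth), length(ps$time))
})

test_that("unperturbed Poincare oscillators settle on the unit cycle", {
  radius_err <- function(h) {
    cfg <- poincare_config(eps1 = 0, eps2_base = 0, eps2_mod = 0,
                           omega1_mod = 0, noise = rep(0, 4),
                           h = h, duration = 50, seed = 1)
    pp <- simulate_poincare_pair(cfg, keep_states = TRUE)
    late <- seq(nrow(pp$states) %/% 2, nrow(pp$states))
    r1 <- sqrt(pp$states$x1[late]^2 + pp$states$y1[late]^2)
    r2 <- sqrt(pp$states$x2[late]^2 + pp$states$y2[late]^2)
    max(abs(c(r1, r2) - 1))
  }
  # the explicit step inflates the cycle radius by about h*omega^2/2,
  # so the attractor is the unit circle in the step-size limit
  expect_lt(radius_err(0.001), 0.02)
  expect_lt(radius_err(0.0005), radius_err(0.002))
})

test_that("noisy Poincare pair has the configured mean phase velocity", {
  pp <- poincare_sim()
  v2 <- mean(diff(pp$phi2)) / pp$h
  expect_equal(v2, 4.91, tolerance = 0.02)
  v1 <- mean(diff(pp$phi1)) / pp$h
  expect_equal(v1, 1, tolerance = 0.15)  # omega1(t) averages to 1
})

test_that("noise-free Poincare trajectory matches a reference integration", {
  cfg <- poincare_config(noise = rep(0, 4), h = 0.001, duration = 20, seed = 1)
  pp <- simulate_poincare_pair(cfg, keep_states = TRUE)
  rhs <- function(t, y, p) {
    w1 <- 1 - 0.4 * sin(2 * pi * cfg$f1 * t)
    e2 <- 0.2 - 0.1 * sin(2 * pi * cfg$f2 * t)
    r1 <- y[1]^2 + y[2]^2 - 1; r2 <- y[3]^2 + y[4]^2 - 1
    list(c(-r1 * y[1] - w1 * y[2] + cfg$eps1 * (y[3] - y[1]),
           -r1 * y[2] + w1 * y[1] + cfg$eps1 * (y[4] - y[2]),
           -r2 * y[3] - cfg$omega2 * y[4] + e2 * (y[1] - y[3]),
           -r2 * y[4] + cfg$omega2 * y[3] + e2 * (y[2] - y[4])))
  }
  ref <- deSolve::ode(c(1, 0, 0, -1), pp$time, rhs, NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(as.matrix(pp$states) - ref[, 2:5])), 0.02)
})

test_that("aperiodic driver is bounded, band-limited and seed-sensitive", {
  d <- aperiodic_driver(600, h = 0.1, seed = 4, band = c(0.1, 0.5))
  expect_equal(range(d$value), c(0.1, 0.5))  # affine rescale contract
  x <- d$value - mean(d$value)
  amp <- Mod(stats::fft(x))[2:(length(x) %/% 2)]
  # chaotic signal: no single spectral line carries most of the variance
  expect_lt(max(amp^2) / sum(amp^2), 0.5)
  d2 <- aperiodic_driver(600, h = 0.1, seed = 4, band = c(0.1, 0.5))
  expect_identical(d$value, d2$value)
  # sensitive dependence: a perturbed initial condition decorrelates
  d3 <- aperiodic_driver(600, h = 0.1, seed = 5, band = c(0.1, 0.5))
  expect_lt(stats::cor(d$value, d3$value), 0.9)
})

test_that("fixture kinds realize their stated frequency laws", {
  fx <- make_fixture("sine", duration = 1200, fs = 10, seed = 1)
  law <- 0.3 + 0.2 * sin(2 * pi * fx$time / 560)
  expect_equal(fx$truth$f1, law, tolerance = 1e-12)
  expect_equal(range(fx$truth$f1), c(0.1, 0.5), tolerance = 0.01)

  fx0 <- make_fixture("free", duration = 300, fs = 10, seed = 1,
                      variability = 0)
  expect_equal(diff(range(fx0$truth$f1)), 0)

  fxa <- make_fixture("aperiodic", duration = 600, fs = 10, seed = 7)
  drv <- aperiodic_driver(600, 0.1, seed = 7, band = c(0.15, 0.45))
  expect_gt(stats::cor(fxa$truth$f1, drv$value), 0.99)
})

test_that("fixture files round-trip through the tabular format", {
  stem <- file.path(tempdir(), "fx")
  fx <- make_fixture("sine", duration = 120, fs = 10, seed = 1, path = stem)
  sig <- read_series(fx$files[["signals"]])
  expect_named(sig, c("time", "sig1", "sig2"))
  expect_equal(attr(sig, "h"), 0.1)
  expect_equal(sig$sig1, fx$sig1, tolerance = 1e-8)
  truth <- read_series(fx$files[["truth"]])
  expect_equal(truth$f1, fx$truth$f1, tolerance = 1e-8)
})
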