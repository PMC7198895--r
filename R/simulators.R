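#' Pair of phase trajectories on a common uniform time grid
#'
#' @param time time grid (s), uniform step.
#' @param phi1,phi2 unwrapped phases (rad), same length as `time`.
#' @param h sampling step (s).
#' @param ground_truth optional data frame on the same grid with the true
#'   time-varying parameters (e.g. columns `omega1`, `a3` or `eps2`).
#' @return a `phase_pair_series` object.
#' @export
phase_pair_series <- function(time, phi1, phi2, h, ground_truth = NULL) {
  stopifnot(length(phi1) == length(time), length(phi2) == length(time), h > 0)
  if (mean(diff(phi1)) <= 0 || mean(diff(phi2)) <= 0) {
    warning("phases do not grow on average; are they unwrapped?")
  }
  structure(
    list(time = time, phi1 = phi1, phi2 = phi2, h = h,
         ground_truth = ground_truth),
    class = "phase_pair_series"
  )
}

#' @export
print.phase_pair_series <- function(x, ...) {
  cat("phase_pair_series:", length(x$time), "samples, h =", format(x$h),
      "s, duration", format(utils::tail(x$time, 1) - x$time[1]), "s\n")
  cat("  mean phase velocities:",
      format(mean(diff(x$phi1)) / x$h, digits = 4), "and",
      format(mean(diff(x$phi2)) / x$h, digits = 4), "rad/s\n")
  invisible(x)
}

#' Configuration of the coupled noisy phase-oscillator test system
#'
#' Two unidirectionally/bidirectionally coupled phase oscillators
#' \deqn{\dot\phi_1 = \omega_1(t) + a_1\sin\phi_1 + a_3(t)\sin\phi_2 + E_{11}\xi_1(t)}
#' \deqn{\dot\phi_2 = \omega_2 + a_2\sin\phi_1 + a_4\sin\phi_2 + E_{22}\xi_2(t)}
#' with slow periodic variation of the first oscillator's frequency and of
#' the coupling amplitude:
#' \deqn{\omega_1(t) = \omega_{1,const} - 0.5\sin(2\pi f_1 t),\quad
#'       a_3(t) = a_{3,const} - 0.3\sin(2\pi f_3 t + \pi/2).}
#' The noises are independent unit-variance Gaussian white processes scaled
#' by the amplitudes `E11`, `E22`.
#'
#' Defaults place the oscillators at cardiorespiratory scales (0.3 Hz and
#' 1.1 Hz) with moderate noise.
#'
#' @param omega1_const,omega2 natural angular frequencies (rad/s).
#' @param a1,a4 self-dynamics amplitudes; `a2`, `a3_const` coupling
#'   amplitudes (dimensionless).
#' @param f1,f3 modulation frequencies of `omega1(t)` and `a3(t)` (Hz).
#' @param omega1_mod,a3_mod modulation amplitudes (defaults 0.5 and 0.3, the
#'   study laws; set to 0 for a stationary system).
#' @param E11,E22 noise amplitudes (>= 0).
#' @param h sampling step (s).
#' @param duration record length (s); must be a whole number of steps.
#' @param seed integer RNG seed.
#' @return a `phase_pair_config` list.
#' @export
phase_pair_config <- function(omega1_const = 2 * pi * 0.3,
                              omega2 = 2 * pi * 1.1,
                              a1 = 0.8, a2 = 0, a3_const = 0.8, a4 = 0.6,
                              f1 = 0.005, f3 = 0.005,
                              omega1_mod = 0.5, a3_mod = 0.3,
                              E11 = 0.3, E22 = 0.3,
                              h = 0.01, duration = 2000, seed = 1L) {
  stopifnot(h > 0, duration > 0, E11 >= 0, E22 >= 0)
  n_steps <- duration / h
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("duration must be a whole number of sampling steps")
  }
  structure(
    list(omega1_const = omega1_const, omega2 = omega2,
         a1 = a1, a2 = a2, a3_const = a3_const, a4 = a4,
         f1 = f1, f3 = f3, omega1_mod = omega1_mod, a3_mod = a3_mod,
         E11 = E11, E22 = E22, h = h, duration = duration,
         seed = as.integer(seed)),
    class = "phase_pair_config"
  )
}

#' Simulate the coupled noisy phase-oscillator pair
#'
#' Euler-Maruyama integration at the sampling step `h`: deterministic drift
#' plus Gaussian increments with standard deviation `E_ii * sqrt(h)`. The
#' true time-varying parameters `omega1(t)` and `a3(t)` are stored on the
#' same grid for later validation of the inference.
#'
#' @param config a [phase_pair_config()].
#' @return a [phase_pair_series()] with `ground_truth` columns `omega1`,
#'   `a3`.
#' @export
simulate_phase_pair <- function(config) {
  stopifnot(inherits(config, "phase_pair_config"))
  h <- config$h
  n <- round(config$duration / h)
  time <- seq(0, by = h, length.out = n + 1)
  omega1_t <- config$omega1_const -
    config$omega1_mod * sin(2 * pi * config$f1 * time)
  a3_t <- config$a3_const -
    config$a3_mod * sin(2 * pi * config$f3 * time + pi / 2)
  set.seed(config$seed)
  z1 <- stats::rnorm(n) * config$E11 * sqrt(h)
  z2 <- stats::rnorm(n) * config$E22 * sqrt(h)
  phi1 <- numeric(n + 1)
  phi2 <- numeric(n + 1)
  for (i in seq_len(n)) {
    p1 <- phi1[i]; p2 <- phi2[i]
    d1 <- omega1_t[i] + config$a1 * sin(p1) + a3_t[i] * sin(p2)
    d2 <- config$omega2 + config$a2 * sin(p1) + config$a4 * sin(p2)
    phi1[i + 1] <- p1 + h * d1 + z1[i]
    phi2[i + 1] <- p2 + h * d2 + z2[i]
  }
  if (!all(is.finite(phi1)) || !all(is.finite(phi2))) {
    stop("simulation diverged (non-finite phase); reduce the step size h")
  }
  phase_pair_series(
    time, phi1, phi2, h,
    ground_truth = data.frame(time = time, omega1 = omega1_t, a3 = a3_t)
  )
}

#' Configuration of the coupled noisy Poincare limit-cycle oscillators
#'
#' Two diffusively coupled Poincare oscillators in the plane,
#' \deqn{\dot x_1 = -(x_1^2+y_1^2-1)x_1 - \omega_1(t) y_1 + \varepsilon_1 (x_2-x_1) + \xi_1(t)}
#' (and symmetrically for the remaining coordinates), with
#' \eqn{\omega_1(t) = 1 - 0.4\sin(2\pi f_1 t)} and time-varying coupling
#' from oscillator 1 to 2, \eqn{\varepsilon_2(t) = 0.2 - 0.1\sin(2\pi f_2 t)}.
#'
#' @param omega2 angular frequency of the second oscillator (rad/s).
#' @param eps1 coupling 2 -> 1 (dimensionless).
#' @param f1,f2 modulation frequencies (Hz) of `omega1(t)` and `eps2(t)`.
#' @param omega1_base,omega1_mod base value and modulation amplitude of
#'   `omega1(t)` (defaults 1 and 0.4, the study laws).
#' @param eps2_base,eps2_mod base value and modulation amplitude of
#'   `eps2(t)` (defaults 0.2 and 0.1).
#' @param noise vector of four noise amplitudes for the four coordinates.
#' @param h sampling step (s).
#' @param duration record length (s).
#' @param seed integer RNG seed.
#' @return a `poincare_config` list.
#' @export
poincare_config <- function(omega2 = 4.91, eps1 = 0.05,
                            f1 = 0.005, f2 = 0.005,
                            omega1_base = 1, omega1_mod = 0.4,
                            eps2_base = 0.2, eps2_mod = 0.1,
                            noise = rep(0.02, 4),
                            h = 0.01, duration = 2000, seed = 1L) {
  stopifnot(h > 0, duration > 0, length(noise) == 4, all(noise >= 0))
  structure(
    list(omega2 = omega2, eps1 = eps1, f1 = f1, f2 = f2,
         omega1_base = omega1_base, omega1_mod = omega1_mod,
         eps2_base = eps2_base, eps2_mod = eps2_mod,
         noise = noise, h = h, duration = duration, seed = as.integer(seed)),
    class = "poincare_config"
  )
}

#' Simulate the coupled noisy Poincare oscillators
#'
#' Euler-Maruyama integration of the four-dimensional stochastic system.
#' Protophases are the planar angles `atan2(y_i, x_i)`, unwrapped.
#'
#' @param config a [poincare_config()].
#' @param keep_states if `TRUE`, attach the raw `(x, y)` trajectories as
#'   element `states`.
#' @return a [phase_pair_series()] with `ground_truth` columns `omega1`,
#'   `eps2`.
#' @export
simulate_poincare_pair <- function(config, keep_states = FALSE) {
  stopifnot(inherits(config, "poincare_config"))
  h <- config$h
  n <- round(config$duration / h)
  time <- seq(0, by = h, length.out = n + 1)
  omega1_t <- config$omega1_base -
    config$omega1_mod * sin(2 * pi * config$f1 * time)
  eps2_t <- config$eps2_base -
    config$eps2_mod * sin(2 * pi * config$f2 * time)
  set.seed(config$seed)
  Z <- matrix(stats::rnorm(4 * n), n, 4)
  Z <- sweep(Z, 2, config$noise * sqrt(h), `*`)
  S <- matrix(0, n + 1, 4)
  S[1, ] <- c(1, 0, 0, -1)  # on the unit cycle, phases well apart
  for (i in seq_len(n)) {
    x1 <- S[i, 1]; y1 <- S[i, 2]; x2 <- S[i, 3]; y2 <- S[i, 4]
    r1 <- x1^2 + y1^2 - 1
    r2 <- x2^2 + y2^2 - 1
    w1 <- omega1_t[i]; e2 <- eps2_t[i]; e1 <- config$eps1
    S[i + 1, 1] <- x1 + h * (-r1 * x1 - w1 * y1 + e1 * (x2 - x1)) + Z[i, 1]
    S[i + 1, 2] <- y1 + h * (-r1 * y1 + w1 * x1 + e1 * (y2 - y1)) + Z[i, 2]
    S[i + 1, 3] <- x2 + h * (-r2 * x2 - config$omega2 * y2 + e2 * (x1 - x2)) + Z[i, 3]
    S[i + 1, 4] <- y2 + h * (-r2 * y2 + config$omega2 * x2 + e2 * (y1 - y2)) + Z[i, 4]
  }
  if (!all(is.finite(S))) {
    stop("simulation diverged (non-finite state); reduce the step size h")
  }
  phi1 <- signal::unwrap(atan2(S[, 2], S[, 1]))
  phi2 <- signal::unwrap(atan2(S[, 4], S[, 3]))
  out <- phase_pair_series(
    time, phi1, phi2, h,
    ground_truth = data.frame(time = time, omega1 = omega1_t, eps2 = eps2_t)
  )
  if (keep_states) {
    out$states <- data.frame(x1 = S[, 1], y1 = S[, 2],
                             x2 = S[, 3], y2 = S[, 4])
  }
  out
}

#' Aperiodic frequency driver from a chaotic Lorenz system
#'
#' Integrates the Lorenz system at the classic chaotic parameters
#' (sigma = 10, rho = 28, beta = 8/3), discards a transient, and affinely
#' rescales the z component into a caller-specified frequency band. The
#' result is a bounded, non-periodic signal suitable as a slowly varying
#' frequency law (e.g. an irregular breathing-rate profile).
#'
#' The Lorenz time axis is compressed by `time_scale` so that the chaotic
#' wandering is slow compared with the oscillations it will drive.
#'
#' @param duration length of the driver (s).
#' @param h sampling step (s).
#' @param seed integer seed (perturbs the initial condition).
#' @param band target band `c(low, high)` in Hz.
#' @param time_scale Lorenz time units per driver second (default 0.05:
#'   one Lorenz lobe switch every few tens of seconds).
#' @return data frame with columns `time` and `value` (Hz); the Lorenz
#'   parameters and scaling are attached as attribute `config`.
#' @export
aperiodic_driver <- function(duration, h, seed = 1L, band = c(0.1, 0.5),
                             time_scale = 0.05) {
  stopifnot(duration > 0, h > 0, length(band) == 2, band[1] < band[2])
  pars <- c(sigma = 10, rho = 28, beta = 8 / 3)
  lorenz <- function(t, y, p) {
    list(c(
      p["sigma"] * (y[2] - y[1]),
      y[1] * (p["rho"] - y[3]) - y[2],
      y[1] * y[2] - p["beta"] * y[3]
    ))
  }
  set.seed(seed)
  y0 <- c(1, 1, 20) + stats::runif(3, -0.5, 0.5)
  transient <- 30  # Lorenz time units
  times <- c(0, transient + seq(0, duration, by = h) * time_scale)
  sol <- deSolve::ode(y0, times, lorenz, pars, method = "ode45",
                      rtol = 1e-8, atol = 1e-8)
  z <- sol[-1, 4]
  if (!all(is.finite(z))) stop("Lorenz integration diverged")
  f <- band[1] + (z - min(z)) / (max(z) - min(z)) * (band[2] - band[1])
  out <- data.frame(time = seq(0, duration, by = h), value = f)
  attr(out, "config") <- list(parameters = pars, initial = y0,
                              transient = transient,
                              time_scale = time_scale, band = band)
  out
}

#' Generate a raw two-signal fixture with known ground truth
#'
#' Emulates a respiration-like signal with a prescribed instantaneous
#' frequency law and a faster heart-like signal whose phase velocity is
#' weakly modulated by the respiration phase. Three frequency laws are
#' available:
#' \describe{
#'   \item{`free`}{constant base rate 0.245 Hz plus slow random variability
#'     (moving-average-filtered Gaussian noise, standard deviation
#'     `variability` Hz);}
#'   \item{`sine`}{`f(t) = 0.3 + 0.2 sin(2 pi t / 560)` Hz;}
#'   \item{`aperiodic`}{a chaotic Lorenz-z driver rescaled into `band`.}
#' }
#' Signals are cosines of the accumulated phases; no attempt is made to
#' reproduce ECG waveform morphology.
#'
#' @param kind `"free"`, `"sine"` or `"aperiodic"`.
#' @param duration record length (s).
#' @param fs sampling rate (Hz); default 10.
#' @param seed integer seed.
#' @param variability slow frequency variability of the `free` law (Hz).
#' @param band frequency band of the `aperiodic` law (Hz).
#' @param heart_rate base heart-like frequency (Hz).
#' @param coupling modulation depth of the heart phase velocity by
#'   `sin(phi_respiration)` (rad/s).
#' @param path optional stem: writes `<path>.tsv` (time, sig1, sig2) and a
#'   ground-truth sidecar `<path>_truth.tsv` (time, f1, phi1, phi2).
#' @return (invisibly when writing) a list with `time`, `sig1`, `sig2`,
#'   `truth` (data frame), `fs`, and the file paths if written.
#' @export
make_fixture <- function(kind = c("free", "sine", "aperiodic"),
                         duration = 1800, fs = 10, seed = 1L,
                         variability = 0.03, band = c(0.15, 0.45),
                         heart_rate = 1.13, coupling = 0.4,
                         path = NULL) {
  kind <- match.arg(kind)
  h <- 1 / fs
  time <- seq(0, duration, by = h)
  n <- length(time)
  set.seed(seed)
  f1 <- switch(kind,
    free = {
      base <- 0.245
      if (variability > 0) {
        # moving-average smoothing over ~30 s gives slow, aperiodic drift
        w <- round(30 * fs)
        e <- stats::filter(stats::rnorm(n + w), rep(1 / w, w), sides = 1)
        e <- e[(w + 1):(w + n)]
        base + variability * (e - mean(e)) / stats::sd(e)
      } else {
        rep(base, n)
      }
    },
    sine = 0.3 + 0.2 * sin(2 * pi * time / 560),
    aperiodic = aperiodic_driver(duration, h, seed = seed, band = band)$value
  )
  phi1 <- 2 * pi * cumsum(c(0, (f1[-n] + f1[-1]) / 2)) * h
  phi2 <- numeric(n)
  for (i in seq_len(n - 1)) {
    phi2[i + 1] <- phi2[i] + h * (2 * pi * heart_rate + coupling * sin(phi1[i]))
  }
  out <- list(
    time = time,
    sig1 = cos(phi1),
    sig2 = cos(phi2),
    truth = data.frame(time = time, f1 = f1, phi1 = phi1, phi2 = phi2),
    fs = fs, kind = kind
  )
  if (!is.null(path)) {
    sig_file <- paste0(path, ".tsv")
    truth_file <- paste0(path, "_truth.tsv")
    write_series(data.frame(time = time, sig1 = out$sig1, sig2 = out$sig2),
                 sig_file)
    write_series(out$truth, truth_file)
    out$files <- c(signals = sig_file, truth = truth_file)
    return(invisible(out))
  }
  out
}
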