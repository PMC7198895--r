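#' Band specification for zero-phase filtering
#'
#' @param low,high band edges (Hz), `0 < low < high < sampling_rate/2`.
#' @param sampling_rate sampling rate (Hz).
#' @return a `band_spec` object.
#' @export
band_spec <- function(low, high, sampling_rate) {
  if (!(0 < low && low < high && high < sampling_rate / 2)) {
    stop("need 0 < low < high < sampling_rate/2 (Nyquist)")
  }
  structure(
    list(low = low, high = high, sampling_rate = sampling_rate),
    class = "band_spec"
  )
}

# FIR order from the band: about three periods of the lowest passband
# frequency, even, and never longer than a third of the record.
default_fir_order <- function(band, n) {
  ord <- round(3 * band$sampling_rate / band$low)
  ord <- min(ord, floor(n / 3) - 1)
  ord <- max(ord, 16)
  if (ord %% 2 == 1) ord <- ord + 1
  ord
}

#' Zero-phase FIR band-pass filter
#'
#' Designs a linear-phase FIR band-pass and applies it forward and backward
#' (`filtfilt`), so the net phase lag is zero and the passband gain is about
#' one.
#'
#' @param x signal vector; its length must well exceed the filter order.
#' @param band a [band_spec()].
#' @param order FIR order; defaults to about three periods of the low band
#'   edge.
#' @return filtered signal, same length as `x`; the order used is attached
#'   as attribute `order`.
#' @export
bandpass_zero_phase <- function(x, band, order = NULL) {
  stopifnot(inherits(band, "band_spec"))
  n <- length(x)
  if (is.null(order)) order <- default_fir_order(band, n)
  if (n <= 3 * order) {
    stop("signal too short (", n, " samples) for FIR order ", order)
  }
  w <- c(band$low, band$high) / (band$sampling_rate / 2)
  b <- signal::fir1(order, w, type = "pass")
  y <- signal::filtfilt(signal::Ma(b), x)
  attr(y, "order") <- order
  y
}

# analytic signal via the frequency-domain Hilbert weighting
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

#' Protophase of an oscillatory signal
#'
#' The angle of the analytic signal (Hilbert embedding) of a zero-mean,
#' band-limited signal. The protophase depends on the observable; use
#' [protophase_to_phase()] to map it to the invariant phase.
#'
#' @param x signal vector (zero-mean, band-limited).
#' @return list with `wrapped` (angles in `[0, 2*pi)`) and `unwrapped`
#'   (cumulative phase, rad).
#' @export
protophase <- function(x) {
  if (stats::sd(x) == 0) {
    stop("constant signal: protophase undefined")
  }
  a <- analytic_signal(x - mean(x))
  th <- atan2(Im(a), Re(a))
  list(wrapped = wrap_phase(th), unwrapped = signal::unwrap(th))
}

#' Protophase-to-phase transformation
#'
#' Maps an observable-dependent protophase \eqn{\theta} to the invariant
#' phase \eqn{\phi} that grows uniformly on average, via the Fourier-series
#' estimate of the protophase density:
#' \deqn{\phi = \theta + \sum_{n=1}^{N_F} 2\,\mathrm{Re}\!\left[S_n
#'   \frac{e^{in\theta} - 1}{in}\right], \qquad S_n = \langle e^{-in\theta}\rangle.}
#' The transformation is 2*pi-periodic (\eqn{\sigma(\theta + 2\pi) =
#' \sigma(\theta) + 2\pi}) and fixes \eqn{\sigma(0) = 0}.
#'
#' @param theta unwrapped protophase covering at least `min_cycles` cycles.
#' @param n_fourier number of Fourier terms of the density estimate.
#' @param amp_threshold terms with `|S_n|` below this are dropped; defaults
#'   to the sampling noise floor `2/sqrt(length(theta))`.
#' @param min_cycles minimum number of cycles required of the input.
#' @return unwrapped invariant phase, same length as `theta`; the retained
#'   Fourier coefficients are attached as attribute `S`.
#' @export
protophase_to_phase <- function(theta, n_fourier = 10, amp_threshold = NULL,
                                min_cycles = 20) {
  span <- diff(range(theta))
  if (span < min_cycles * 2 * pi) {
    stop("protophase covers only ", round(span / (2 * pi), 1),
         " cycles; at least ", min_cycles,
         " are needed -- provide a longer record")
  }
  if (is.null(amp_threshold)) amp_threshold <- 2 / sqrt(length(theta))
  ns <- seq_len(n_fourier)
  S <- vapply(ns, function(n) mean(exp(-1i * n * theta)), complex(1))
  keep <- Mod(S) >= amp_threshold
  phi <- theta
  for (n in ns[keep]) {
    phi <- phi + 2 * Re(S[n] * (exp(1i * n * theta) - 1) / (1i * n))
  }
  attr(phi, "S") <- S[keep]
  attr(phi, "n_terms") <- sum(keep)
  phi
}

#' Extract invariant phases from a raw signal pair
#'
#' Chains the full extraction protocol for each channel: zero-phase FIR
#' band-pass, analytic-signal protophase, protophase-to-phase
#' transformation, and finally discards an edge margin where the filter
#' transients live.
#'
#' @param time time grid (s).
#' @param sig1,sig2 raw signal vectors.
#' @param band1,band2 [band_spec()]s for the two channels (e.g. a
#'   respiratory band 0.145-0.6 Hz and a cardiac band 0.6-2 Hz).
#' @param transform apply [protophase_to_phase()] (default `TRUE`).
#' @param margin_factor edge margin to discard, in units of the (longest)
#'   filter length; default 3.
#' @return a [phase_pair_series()] on the trimmed grid.
#' @export
extract_phases <- function(time, sig1, sig2, band1, band2,
                           transform = TRUE, margin_factor = 3) {
  h <- stats::median(diff(time))
  f1 <- bandpass_zero_phase(sig1, band1)
  f2 <- bandpass_zero_phase(sig2, band2)
  th1 <- protophase(f1)$unwrapped
  th2 <- protophase(f2)$unwrapped
  if (transform) {
    th1 <- as.numeric(protophase_to_phase(th1))
    th2 <- as.numeric(protophase_to_phase(th2))
  }
  margin <- margin_factor * max(attr(f1, "order"), attr(f2, "order"))
  n <- length(time)
  if (2 * margin >= n - 10) {
    stop("record too short for the filter edge margin")
  }
  keep <- (margin + 1):(n - margin)
  phase_pair_series(time[keep], th1[keep], th2[keep], h)
}
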