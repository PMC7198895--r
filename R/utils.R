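#' Wrap phases onto [0, 2*pi)
#'
#' @param phi numeric vector of phases in radians (wrapped or unwrapped).
#' @return numeric vector in `[0, 2*pi)`.
#' @export
wrap_phase <- function(phi) {
  phi %% (2 * pi)
}

#' Convert a per-minute event rate to Hertz
#'
#' Breathing and heart rates are conventionally reported per minute
#' (breaths/min, beats/min); the oscillator models work in Hz.
#'
#' @param per_minute rate in events per minute.
#' @return rate in Hz.
#' @examples
#' per_minute_to_hz(14.7) # 0.245 Hz
#' @export
per_minute_to_hz <- function(per_minute) {
  per_minute / 60
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_dbi <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "dbiwin_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# least-squares amplitude of a sinusoidal component at a known frequency;
# used to quantify how much of a parameter's true modulation the inference
# recovered.
#' Fitted amplitude of a sinusoid at a known frequency
#'
#' Fits `y ~ m + a*sin(2*pi*f*t) + b*cos(2*pi*f*t)` by least squares and
#' returns `sqrt(a^2 + b^2)`.
#'
#' @param time sample times (s).
#' @param values series sampled at `time`.
#' @param freq frequency of the fitted sinusoid (Hz).
#' @return nonnegative amplitude estimate.
#' @export
modulation_amplitude <- function(time, values, freq) {
  stopifnot(length(time) == length(values), freq > 0)
  X <- cbind(1, sin(2 * pi * freq * time), cos(2 * pi * freq * time))
  cf <- stats::lm.fit(X, values)$coefficients
  sqrt(cf[2]^2 + cf[3]^2)
}
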