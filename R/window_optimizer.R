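#' Smallest time window for which sequential inference runs
#'
#' Scans increasing window lengths, starting from the information floor of
#' four velocity samples per base function, and returns the first for which
#' [run_sequential()] completes without a singular-matrix failure. Below
#' this value the concentration matrix is rank-deficient and the recursion
#' cannot produce an output.
#'
#' @param phases a [phase_pair_series()].
#' @param p_w propagation parameter used during the scan (default 0.2).
#' @param K Fourier order.
#' @param growth multiplicative step of the scan grid.
#' @return feasible window length (s), snapped to a whole number of samples.
#' @export
smallest_feasible_window <- function(phases, p_w = 0.2, K = 2,
                                     growth = 1.25) {
  model <- fourier_model(K)
  h <- phases$h
  duration <- (length(phases$phi1) - 1) * h
  t_w <- 4 * model$n_basis * h   # minimum samples per basis dimension
  while (t_w <= duration / 8) {
    t_w <- round(t_w / h) * h
    ok <- tryCatch({
      run_sequential(phases, inference_settings(t_w = t_w, p_w = p_w, K = K))
      TRUE
    }, dbiwin_singular = function(e) FALSE)
    if (ok) return(t_w)
    t_w <- t_w * growth
  }
  stop("no feasible time window below an eighth of the record length")
}

#' Highest significant frequency of parameter variation
#'
#' Computes the discrete Fourier amplitude spectrum of every inferred
#' parameter's block-wise time series (mean removed, first `exclude_first`
#' blocks dropped) and returns the highest frequency at which any
#' parameter's amplitude exceeds a significance threshold, expressed as a
#' multiple of that parameter's median spectral amplitude.
#'
#' The first pass of the optimization runs at the shortest usable window,
#' where occasional ill-conditioned blocks yield outlying parameter
#' estimates whose broadband spectral splatter would masquerade as
#' high-frequency variability. Each series is therefore winsorized at
#' `median +/- 5 MAD` before the transform.
#'
#' Two conditions make a spectral line significant: it must exceed
#' `threshold` times the local spectral background of its own parameter --
#' the median amplitude over the neighbouring frequency bins -- and it
#' must reach at least `rel_threshold` of the largest line found in any
#' parameter. The local background is what separates a genuine line from
#' estimation noise: the between-block prior propagation makes the
#' estimates wander slowly, producing a smooth low-frequency-heavy noise
#' spectrum in every parameter, and no bin of a smooth spectrum stands
#' far above its neighbours. The relative floor discards variations an
#' order of magnitude below the dominant one, which contribute negligibly
#' to the parameter dynamics. Series are Hann-tapered so that leakage
#' skirts of strong off-bin lines do not inflate `f_max`.
#'
#' Parameters whose block series merely reflect estimation uncertainty are
#' screened out up front: a parameter enters the line search only if the
#' variance of its (winsorized) series exceeds `var_screen` times its mean
#' posterior variance. A well-calibrated estimate of a constant parameter
#' has a series variance close to its posterior variance, while genuine
#' time-variation adds to it.
#'
#' @param run an `inference_run` with at least 16 blocks.
#' @param threshold significance multiple of the local background
#'   (default 5).
#' @param rel_threshold minimum amplitude relative to the largest
#'   significant line (default 0.1).
#' @param var_screen minimum ratio of block-series variance to mean
#'   posterior variance for a parameter to be searched (default 1.5).
#' @param exclude_first leading blocks to drop (default 2).
#' @return list with `f_max` (Hz), `T_min` (s), and `spectra` (data frame
#'   of frequency, amplitude, parameter index for the significant peaks of
#'   each parameter).
#' @export
estimate_fmax <- function(run, threshold = 5, rel_threshold = 0.1,
                          var_screen = 1.5, exclude_first = 2) {
  cm <- coef_matrix(run)
  if (nrow(cm) < 16) {
    stop("need at least 16 blocks to estimate the parameter spectrum; ",
         "re-run with a shorter time window")
  }
  cm <- cm[-seq_len(exclude_first), , drop = FALSE]
  post_var <- colMeans(do.call(rbind, lapply(
    run$states[-seq_len(exclude_first)], function(s) diag(s$Sigma)
  )))
  n <- nrow(cm)
  dt <- run$settings$t_w
  n_pos <- floor(n / 2)
  freqs <- (1:n_pos) / (n * dt)
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  spectra <- vector("list", ncol(cm))
  for (j in seq_len(ncol(cm))) {
    x <- cm[, j]
    md <- stats::median(x)
    bound <- 5 * stats::mad(x)
    if (bound > 0) x <- pmin(pmax(x, md - bound), md + bound)
    if (stats::var(x) < var_screen * post_var[j]) next
    x <- (x - mean(x)) * taper
    amp <- (2 / n) * Mod(stats::fft(x))[2:(n_pos + 1)]
    # robust local background: +/-10 bins, with a +/-1 guard band for the
    # Hann mainlobe of the candidate line itself
    local_bg <- vapply(seq_len(n_pos), function(k) {
      w <- setdiff(max(1, k - 10):min(n_pos, k + 10), (k - 1):(k + 1))
      stats::median(amp[w])
    }, numeric(1))
    # candidate lines need at least ~5 observed periods: the stochastic
    # wander of the estimates concentrates its power in the first few
    # bins, where it is indistinguishable from genuine slow variability
    sig <- amp > 0 & amp >= threshold * local_bg & seq_len(n_pos) >= 5
    if (any(sig)) {
      spectra[[j]] <- data.frame(parameter = j, frequency = freqs[sig],
                                 amplitude = amp[sig])
    }
  }
  peaks <- do.call(rbind, spectra)
  if (!is.null(peaks)) {
    peaks <- peaks[peaks$amplitude >= rel_threshold * max(peaks$amplitude), ]
  }
  if (is.null(peaks) || nrow(peaks) == 0) {
    stop("no detectable time-variability in any inferred parameter ",
         "(no spectral peak above ", threshold,
         "x the median amplitude); the dynamics may be stationary -- ",
         "any fixed time window is then adequate")
  }
  f_max <- max(peaks$frequency)
  list(f_max = f_max, T_min = 1 / f_max, spectra = peaks)
}

#' Optimal time window from the fastest parameter variation
#'
#' Eight blocks are needed to resolve one period of the fastest-changing
#' parameter, so the window is an eighth of the shortest variation period:
#' `t_w_opt = T_min / 8 = 1 / (8 * f_max)`.
#'
#' @param f_max highest significant frequency of parameter change (Hz).
#' @return optimal window length (s).
#' @export
optimal_window <- function(f_max) {
  if (!is.numeric(f_max) || f_max <= 0) stop("f_max must be positive")
  1 / (8 * f_max)
}

#' Optimal propagation parameter from the optimal window
#'
#' Piecewise selection rule calibrated for cardiorespiratory-scale dynamics
#' with non-negligible noise:
#' \deqn{p_{w,opt} = \cases{0.1 & t_{w,opt} > 40 \cr
#'                          0.2 & t_{w,opt} \in [10, 40] \cr
#'                          2 / t_{w,opt} & t_{w,opt} < 10.}}
#'
#' @param t_w_opt optimal window length (s).
#' @return optimal propagation parameter (dimensionless).
#' @export
optimal_propagation <- function(t_w_opt) {
  stopifnot(t_w_opt > 0)
  if (t_w_opt > 40) 0.1
  else if (t_w_opt >= 10) 0.2
  else 2 / t_w_opt
}

#' Two-pass determination of the window and propagation parameter
#'
#' Pass 1 runs sequential inference with a small window (the smallest
#' feasible one unless `initial_t_w` is given) and `p_w = 0.2`; the
#' block-wise parameter series then yield the highest frequency of
#' parameter variation, from which the optimal window
#' (`1/(8 f_max)`) and propagation parameter (piecewise rule) follow.
#' Pass 2 re-runs the inference at the optimized settings, which tightens
#' the posteriors (smaller block-mean quadrature covariance).
#'
#' @param phases a [phase_pair_series()].
#' @param initial_t_w optional window (s) for the first pass.
#' @param initial_p_w propagation parameter for the first pass.
#' @param K Fourier order.
#' @param threshold spectral significance threshold of [estimate_fmax()].
#' @return list with elements
#'   \item{plan}{a `window_plan`: `f_max`, `T_min`, `t_w_opt`, `p_w_opt`,
#'     `initial_t_w`, `spectra`,}
#'   \item{run}{the optimized `inference_run`,}
#'   \item{initial_run}{the first-pass run.}
#' @export
optimize_inference <- function(phases, initial_t_w = NULL,
                               initial_p_w = 0.2, K = 2, threshold = 5) {
  if (is.null(initial_t_w)) {
    initial_t_w <- smallest_feasible_window(phases, p_w = initial_p_w, K = K)
  }
  run1 <- run_sequential(
    phases, inference_settings(t_w = initial_t_w, p_w = initial_p_w, K = K)
  )
  est <- estimate_fmax(run1, threshold = threshold)
  t_w_opt <- optimal_window(est$f_max)
  p_w_opt <- optimal_propagation(t_w_opt)
  duration <- (length(phases$phi1) - 1) * phases$h
  if (t_w_opt > duration / 2) {
    stop("optimal window (", round(t_w_opt, 1),
         " s) exceeds half the record; record too short for the detected ",
         "variability")
  }
  run2 <- run_sequential(
    phases, inference_settings(t_w = t_w_opt, p_w = p_w_opt, K = K)
  )
  plan <- structure(
    list(f_max = est$f_max, T_min = est$T_min,
         t_w_opt = t_w_opt, p_w_opt = p_w_opt,
         initial_t_w = initial_t_w, spectra = est$spectra),
    class = "window_plan"
  )
  list(plan = plan, run = run2, initial_run = run1)
}

#' @export
print.window_plan <- function(x, ...) {
  cat("window_plan\n")
  cat("  f_max    :", format(x$f_max, digits = 4), "Hz  (T_min =",
      format(x$T_min, digits = 4), "s)\n")
  cat("  t_w_opt  :", format(x$t_w_opt, digits = 4), "s\n")
  cat("  p_w_opt  :", format(x$p_w_opt, digits = 4), "\n")
  cat("  first pass used t_w =", format(x$initial_t_w, digits = 4), "s\n")
  invisible(x)
}

#' Quadrature-covariance surface over (t_w, p_w)
#'
#' Runs sequential inference for every grid combination and records the
#' block-mean quadrature covariance; for each `p_w` the maximizing window
#' `t_w_max` is located on the grid (no interpolation). Windows are snapped
#' to whole numbers of samples; infeasible grid points are recorded as `NA`.
#'
#' @param phases a [phase_pair_series()].
#' @param t_w_grid vector of window lengths (s).
#' @param p_w_grid vector of propagation parameters.
#' @param K Fourier order.
#' @return a `qsigma_surface`: list with `t_w` (snapped grid), `p_w`,
#'   `q_sigma` (matrix, rows = t_w, cols = p_w), `t_w_max` (per p_w).
#' @export
qsigma_surface <- function(phases, t_w_grid, p_w_grid, K = 2) {
  h <- phases$h
  t_w_grid <- round(t_w_grid / h) * h
  Q <- matrix(NA_real_, length(t_w_grid), length(p_w_grid),
              dimnames = list(format(t_w_grid), format(p_w_grid)))
  for (jp in seq_along(p_w_grid)) {
    for (jt in seq_along(t_w_grid)) {
      Q[jt, jp] <- tryCatch(
        mean_qsigma(run_sequential(
          phases,
          inference_settings(t_w = t_w_grid[jt], p_w = p_w_grid[jp], K = K)
        )),
        dbiwin_singular = function(e) NA_real_,
        error = function(e) NA_real_
      )
    }
  }
  t_w_max <- apply(Q, 2, function(col) {
    if (all(is.na(col))) NA_real_ else t_w_grid[which.max(col)]
  })
  structure(
    list(t_w = t_w_grid, p_w = p_w_grid, q_sigma = Q, t_w_max = t_w_max),
    class = "qsigma_surface"
  )
}

#' @export
print.qsigma_surface <- function(x, ...) {
  cat("qsigma_surface:", length(x$t_w), "windows x", length(x$p_w),
      "propagation values\n")
  for (j in seq_along(x$p_w)) {
    cat("  p_w =", format(x$p_w[j]), ": t_w_max =",
        format(x$t_w_max[j]), "s\n")
  }
  invisible(x)
}

#' Block-wise error of inferred parameters against ground truth
#'
#' Compares selected inferred parameter series with known true parameter
#' laws: the truth is averaged within each block (same time support as the
#' inference) and the block-wise differences and their mean square error
#' are returned, excluding the first `exclude_first` blocks.
#'
#' @param run an `inference_run`.
#' @param truth data frame with a `time` column and one column per tracked
#'   parameter, on the simulation grid.
#' @param mapping named integer vector: for each truth column, the index of
#'   the corresponding entry of the model parameter vector (see
#'   [basis_index()]).
#' @param exclude_first leading blocks to drop (default 2).
#' @return list with `delta` (data frame of block time and per-parameter
#'   differences `inferred - true`) and `mse` (named vector).
#' @export
validation_mse <- function(run, truth, mapping, exclude_first = 2) {
  stopifnot(is.data.frame(truth), "time" %in% names(truth),
            all(names(mapping) %in% names(truth)))
  cm <- coef_matrix(run)
  t_w <- run$settings$t_w
  keep <- setdiff(seq_len(nrow(cm)), seq_len(exclude_first))
  bt <- run$block_times[keep]
  delta <- data.frame(time = bt)
  mse <- numeric(0)
  for (nm in names(mapping)) {
    true_block <- vapply(bt, function(t0) {
      inside <- truth$time >= t0 - t_w / 2 & truth$time < t0 + t_w / 2
      mean(truth[[nm]][inside])
    }, numeric(1))
    d <- cm[keep, mapping[[nm]]] - true_block
    delta[[nm]] <- d
    mse[nm] <- mean(d^2)
  }
  list(delta = delta, mse = mse)
}
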