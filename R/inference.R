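#' Settings for sequential dynamical Bayesian inference
#'
#' @param t_w block length (time window) in seconds. Each posterior is
#'   computed from one block; `t_w` sets the time resolution of the inferred
#'   parameters.
#' @param p_w propagation parameter: the fraction of each parameter used as
#'   the standard deviation of its between-block diffusion when the posterior
#'   covariance is widened into the next block's prior.
#' @param K Fourier order of the phase model (see [fourier_model()]).
#' @param tol relative change of the parameter vector below which the
#'   within-block recursion is declared converged.
#' @param max_iter maximum number of within-block iterations.
#' @return an `inference_settings` object.
#' @export
inference_settings <- function(t_w, p_w, K = 2, tol = 1e-6, max_iter = 100) {
  stopifnot(t_w > 0, p_w >= 0, max_iter >= 1, tol > 0)
  structure(
    list(t_w = t_w, p_w = p_w, K = K, tol = tol, max_iter = max_iter),
    class = "inference_settings"
  )
}

new_model_state <- function(c, E, Xi, Sigma, block_time = NA_real_,
                            converged = TRUE) {
  structure(
    list(c = c, E = E, Xi = Xi, Sigma = Sigma, block_time = block_time,
         converged = converged),
    class = "model_state"
  )
}

#' Non-informative prior state
#'
#' A flat prior: zero parameter mean and zero concentration (infinite
#' covariance), used for the first block of a sequential run.
#'
#' @param model a [fourier_model()].
#' @return a `model_state` with zero mean and zero concentration.
#' @export
flat_prior <- function(model = fourier_model()) {
  d <- 2 * model$n_basis
  new_model_state(
    c = numeric(d),
    E = diag(2) * NA_real_,
    Xi = matrix(0, d, d),
    Sigma = matrix(Inf, d, d),
    block_time = NA_real_
  )
}

#' @export
print.model_state <- function(x, ...) {
  cat("model_state:", length(x$c), "parameters")
  if (!is.na(x$block_time)) cat(", block time", format(x$block_time), "s")
  cat("\n  inferred noise (sqrt of diagonal of E):",
      paste(format(sqrt(pmax(diag(x$E), 0)), digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

# Sufficient statistics of one block: design matrix Gram blocks evaluated at
# interval midpoints, with finite-difference phase velocities. These do not
# depend on (c, E), so the within-block recursion only needs F x F algebra.
block_stats <- function(phi1, phi2, h, model) {
  n <- length(phi1) - 1
  mid1 <- (phi1[-1] + phi1[-(n + 1)]) / 2
  mid2 <- (phi2[-1] + phi2[-(n + 1)]) / 2
  dphi <- cbind((phi1[-1] - phi1[-(n + 1)]) / h,
                (phi2[-1] - phi2[-(n + 1)]) / h)
  eb <- evaluate_basis(mid1, mid2, model)
  list(
    n = n,
    G = crossprod(eb$Phi),                       # F x F
    tPd = crossprod(eb$Phi, dphi),               # F x 2
    dsum = cbind(colSums(eb$dPhi1), colSums(eb$dPhi2)),  # F x 2 drift sums
    Sdd = crossprod(dphi)                        # 2 x 2
  )
}

# Noise floor used when a block is fitted (numerically) perfectly; keeps the
# concentration matrix finite without influencing any realistic fit.
.E_FLOOR <- 1e-14

#' Bayesian parameter update for one block of phase data
#'
#' Iterates the stationary-point recursion of dynamical Bayesian inference on
#' one block: the noise matrix is re-estimated from the residuals of the
#' finite-difference phase velocities against the current model, the
#' parameter mean is obtained from the concentration-weighted normal
#' equations (including the prior term and the Jacobian drift correction),
#' and the concentration matrix is the prior concentration plus the data
#' term. With a flat prior and vanishing noise the parameter mean coincides
#' with ordinary least squares of the phase velocities on the basis.
#'
#' Noise cross-correlations are fixed at zero: only the diagonal of the
#' noise matrix is estimated.
#'
#' @param phases a [phase_pair_series()] (or any list with `phi1`, `phi2`,
#'   `h`) holding the samples of one block.
#' @param prior a `model_state` prior (see [flat_prior()],
#'   [propagate_prior()]).
#' @param settings an [inference_settings()].
#' @param block_time time stamp to attach to the state (s).
#' @return posterior `model_state`.
#' @export
infer_block <- function(phases, prior = NULL, settings, block_time = NA_real_) {
  model <- fourier_model(settings$K)
  F <- model$n_basis
  if (is.null(prior)) prior <- flat_prior(model)
  n_samp <- length(phases$phi1)
  if (n_samp - 1 < 4 * F) {
    stop_dbi(
      sprintf(
        "block too short: %d velocity samples for %d base functions (need >= %d); Singular matrix risk",
        n_samp - 1, F, 4 * F
      ),
      "dbiwin_singular"
    )
  }
  bs <- block_stats(phases$phi1, phases$phi2, phases$h, model)
  h <- phases$h
  cp <- prior$c
  Xip <- prior$Xi
  cc <- cp
  converged <- FALSE
  for (iter in seq_len(settings$max_iter)) {
    Cm <- matrix(cc, F, 2)
    RR <- bs$Sdd - crossprod(Cm, bs$tPd) - crossprod(bs$tPd, Cm) +
      crossprod(Cm, bs$G %*% Cm)
    Ed <- pmax(h * diag(RR) / bs$n, .E_FLOOR)
    Einv <- diag(1 / Ed)
    Xi <- Xip + h * kronecker(Einv, bs$G)
    Rm <- bs$tPd %*% Einv - 0.5 * bs$dsum
    r <- as.vector(Xip %*% cp) + h * as.vector(Rm)
    cnew <- tryCatch(
      solve(Xi, r),
      error = function(e) {
        stop_dbi(
          paste0("Singular matrix error in block update: ", conditionMessage(e)),
          "dbiwin_singular"
        )
      }
    )
    step <- sqrt(sum((cnew - cc)^2)) / max(sqrt(sum(cc^2)), 1e-12)
    cc <- cnew
    if (step < settings$tol) {
      converged <- TRUE
      break
    }
  }
  Sigma <- tryCatch(
    solve(Xi),
    error = function(e) {
      stop_dbi("Singular matrix error inverting concentration matrix",
               "dbiwin_singular")
    }
  )
  new_model_state(
    c = as.vector(cc),
    E = diag(Ed),
    Xi = Xi,
    Sigma = Sigma,
    block_time = block_time,
    converged = converged
  )
}

#' Diffusion propagation of the posterior into the next block's prior
#'
#' The prior covariance for block n+1 is the posterior covariance of block n
#' widened by a diagonal diffusion matrix whose standard deviations are a
#' fixed fraction of the current parameters, `sigma_i = p_w * c_i`
#' (parameter changes are taken as uncorrelated). The parameter means are
#' carried forward unchanged.
#'
#' @param post posterior `model_state`.
#' @param settings an [inference_settings()] supplying `p_w`.
#' @return prior `model_state` for the next block.
#' @export
propagate_prior <- function(post, settings) {
  sig2 <- (settings$p_w * post$c)^2
  Sigma_prior <- post$Sigma + diag(sig2, length(sig2))
  Xi_prior <- tryCatch(
    solve(Sigma_prior),
    error = function(e) {
      stop_dbi("propagated covariance is not invertible", "dbiwin_singular")
    }
  )
  new_model_state(
    c = post$c,
    E = post$E,
    Xi = Xi_prior,
    Sigma = Sigma_prior,
    block_time = post$block_time
  )
}

#' Quadrature covariance matrix
#'
#' Sum of squares of all elements of a covariance matrix: a scalar indicator
#' of the spread of the inferred parameters (smaller values indicate tighter
#' posteriors).
#'
#' @param Sigma square covariance matrix.
#' @return nonnegative scalar.
#' @export
quadrature_covariance <- function(Sigma) {
  stopifnot(is.matrix(Sigma), nrow(Sigma) == ncol(Sigma))
  sum(Sigma^2)
}

#' Sequential dynamical Bayesian inference over consecutive blocks
#'
#' Partitions the phase series into consecutive non-overlapping blocks of
#' length `t_w` (snapped to a whole number of samples) and chains
#' [infer_block()] with [propagate_prior()], so that each block's posterior
#' informs the next block's prior. The first block uses a flat prior.
#'
#' @param phases a [phase_pair_series()].
#' @param settings an [inference_settings()].
#' @return an `inference_run`: list with `states` (one `model_state` per
#'   block), `q_sigma` (per-block quadrature covariance), `block_times`
#'   (block mid-times, s), `settings`, `model`, `h`.
#' @export
run_sequential <- function(phases, settings) {
  h <- phases$h
  n_b <- round(settings$t_w / h)
  if (n_b < 2) stop("time window shorter than two samples")
  n_pairs <- length(phases$phi1) - 1
  n_blocks <- floor(n_pairs / n_b)
  if (n_blocks < 2) {
    stop("series must be at least two time windows long")
  }
  model <- fourier_model(settings$K)
  states <- vector("list", n_blocks)
  q_sigma <- numeric(n_blocks)
  block_times <- numeric(n_blocks)
  prior <- flat_prior(model)
  for (b in seq_len(n_blocks)) {
    i0 <- (b - 1) * n_b + 1
    idx <- i0:(i0 + n_b)           # one overlapping sample between blocks
    blk <- list(phi1 = phases$phi1[idx], phi2 = phases$phi2[idx], h = h)
    bt <- mean(phases$time[idx])
    post <- tryCatch(
      infer_block(blk, prior, settings, block_time = bt),
      dbiwin_singular = function(e) {
        stop_dbi(
          sprintf("block %d of %d: %s", b, n_blocks, conditionMessage(e)),
          "dbiwin_singular"
        )
      }
    )
    states[[b]] <- post
    q_sigma[b] <- quadrature_covariance(post$Sigma)
    block_times[b] <- bt
    if (b < n_blocks) prior <- propagate_prior(post, settings)
  }
  structure(
    list(states = states, q_sigma = q_sigma, block_times = block_times,
         settings = settings, model = model, h = h),
    class = "inference_run"
  )
}

#' @export
print.inference_run <- function(x, ...) {
  cat("inference_run:", length(x$states), "blocks, t_w =",
      format(x$settings$t_w), "s, p_w =", format(x$settings$p_w), "\n")
  cat("  mean Q_Sigma (blocks 3..n):", format(mean_qsigma(x)), "\n")
  invisible(x)
}

#' Block-wise parameter matrix of a run
#'
#' @param run an `inference_run`.
#' @return numeric matrix, one row per block, one column per model parameter
#'   (oscillator 1's coefficients then oscillator 2's).
#' @export
coef_matrix <- function(run) {
  do.call(rbind, lapply(run$states, function(s) s$c))
}

#' Block-averaged quadrature covariance of a run
#'
#' Early blocks reflect the arbitrary initial prior, so the first
#' `exclude_first` blocks are omitted from the average.
#'
#' @param run an `inference_run`.
#' @param exclude_first number of leading blocks to drop (default 2).
#' @return scalar mean quadrature covariance.
#' @export
mean_qsigma <- function(run, exclude_first = 2) {
  q <- run$q_sigma
  if (length(q) > exclude_first) q <- q[-seq_len(exclude_first)]
  mean(q)
}
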