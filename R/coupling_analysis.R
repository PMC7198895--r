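#' Coupling-function surface on the wrapped phase grid
#'
#' Evaluates the coupling function \eqn{q_i(\phi_i, \phi_j)} of one
#' oscillator from the cross terms of an inferred state -- the base
#' functions that depend on the partner oscillator's phase, scaled by their
#' inferred coefficients (constant and self terms are excluded) -- on a
#' regular 2*pi x 2*pi grid.
#'
#' @param state a `model_state` (or any list with element `c`).
#' @param which oscillator index, 1 or 2.
#' @param model the [fourier_model()] used for the inference.
#' @param resolution grid points per axis (>= 8, default 100).
#' @return a `coupling_surface`: list with `phi_own`, `phi_other` (grid
#'   axes for the named oscillator's own and the partner's phase), `values`
#'   (matrix, rows = own phase), `which`, `block_time`.
#' @export
coupling_surface <- function(state, which = 2, model = fourier_model(),
                             resolution = 100) {
  stopifnot(which %in% c(1, 2))
  if (resolution < 8) stop("resolution must be at least 8")
  g <- seq(0, 2 * pi, length.out = resolution + 1)[1:resolution]
  # rows: own phase, columns: partner phase
  own <- rep(g, times = resolution)
  oth <- rep(g, each = resolution)
  if (which == 1) {
    eb <- evaluate_basis(own, oth, model)
  } else {
    eb <- evaluate_basis(oth, own, model)
  }
  idx <- coupling_indices(model, which)
  local_idx <- idx - (which - 1) * model$n_basis
  vals <- eb$Phi[, local_idx, drop = FALSE] %*% state$c[idx]
  structure(
    list(phi_own = g, phi_other = g,
         values = matrix(vals, resolution, resolution),
         which = which,
         block_time = state$block_time %||% NA_real_),
    class = "coupling_surface"
  )
}

#' @export
print.coupling_surface <- function(x, ...) {
  cat("coupling_surface: q_", x$which, " on ", length(x$phi_own), "x",
      length(x$phi_other), " grid, range [",
      format(min(x$values), digits = 3), ", ",
      format(max(x$values), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Write a coupling surface as plain matrix text
#'
#' One header line (`# oscillator, resolution, block time`) followed by the
#' value matrix, rows indexed by the oscillator's own phase.
#'
#' @param surface a [coupling_surface()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_surface <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# oscillator %d, resolution %d, block_time %s",
                     surface$which, length(surface$phi_own),
                     format(surface$block_time)), con)
  utils::write.table(surface$values, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coupling strength of an inferred state
#'
#' Euclidean norm of the inferred cross-term (coupling) parameter
#' subvector of one oscillator.
#'
#' @inheritParams coupling_surface
#' @return nonnegative scalar.
#' @export
coupling_strength <- function(state, which = 2, model = fourier_model()) {
  sqrt(sum(state$c[coupling_indices(model, which)]^2))
}

#' Similarity index of two coupling functions
#'
#' Pearson correlation of two coupling-parameter vectors: quantifies the
#' similarity of the coupling-function forms irrespective of their
#' amplitudes (invariant under positive rescaling of either vector).
#'
#' @param a,b equal-length coupling-parameter vectors.
#' @return scalar in `[-1, 1]`.
#' @export
similarity_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance coupling vector: similarity undefined")
  }
  stats::cor(a, b)
}

#' Time-resolved coupling strength and similarity of a run
#'
#' For each block, the coupling strengths `CPL_1(t)`, `CPL_2(t)` and, per
#' direction, the similarity index between that block's coupling-parameter
#' vector and the time-averaged one (the mean over blocks, i.e. the
#' time-averaged coupling function -- the basis expansion is linear, so the
#' mean parameter vector represents the mean surface).
#'
#' @param run an `inference_run` with at least 3 blocks.
#' @return data frame with columns `time`, `cpl1`, `cpl2`, `rho1`, `rho2`;
#'   the mean coupling-parameter vectors are attached as attribute
#'   `mean_coupling`.
#' @export
time_resolved_similarity <- function(run) {
  cm <- coef_matrix(run)
  if (nrow(cm) < 3) stop("need at least 3 blocks")
  model <- run$model
  idx1 <- coupling_indices(model, 1)
  idx2 <- coupling_indices(model, 2)
  c1 <- cm[, idx1, drop = FALSE]
  c2 <- cm[, idx2, drop = FALSE]
  m1 <- colMeans(c1)
  m2 <- colMeans(c2)
  out <- data.frame(
    time = run$block_times,
    cpl1 = sqrt(rowSums(c1^2)),
    cpl2 = sqrt(rowSums(c2^2)),
    rho1 = apply(c1, 1, similarity_index, b = m1),
    rho2 = apply(c2, 1, similarity_index, b = m2)
  )
  attr(out, "mean_coupling") <- list(q1 = m1, q2 = m2)
  out
}
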