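#' Read a uniformly sampled time-series table
#'
#' Reads a delimited text file with a header row and a leading `time`
#' column. The delimiter is auto-detected (tab or comma). The time grid is
#' checked for uniformity; the first offending row is named on failure.
#'
#' @param path file path.
#' @param tol_rel maximum allowed relative deviation of successive steps
#'   from the median step.
#' @return data frame with the file's columns; the sampling step is attached
#'   as attribute `h`.
#' @export
read_series <- function(path, tol_rel = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) {
    stop("missing 'time' column in ", path)
  }
  if (ncol(df) < 2) stop("expected at least one signal column in ", path)
  steps <- diff(df$time)
  h <- stats::median(steps)
  if (any(steps <= 0)) {
    stop("time column not strictly increasing at row ",
         which(steps <= 0)[1] + 1)
  }
  bad <- which(abs(steps - h) > tol_rel * h)
  if (length(bad) > 0) {
    stop("non-uniform time grid at row ", bad[1] + 1,
         " (step ", format(steps[bad[1]]), ", expected ", format(h), ")")
  }
  attr(df, "h") <- h
  df
}

#' Write a time-series table as tab-separated text
#'
#' @param df data frame with a `time` column.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_series <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a phase table as a phase_pair_series
#'
#' Expects columns `time`, `phi1`, `phi2` as written by
#' [write_phase_series()].
#'
#' @param path file path.
#' @return a [phase_pair_series()].
#' @export
read_phase_series <- function(path) {
  df <- read_series(path)
  if (!all(c("phi1", "phi2") %in% names(df))) {
    stop("expected columns phi1, phi2 in ", path)
  }
  phase_pair_series(df$time, df$phi1, df$phi2, attr(df, "h"))
}

#' @rdname read_phase_series
#' @param phases a [phase_pair_series()].
#' @export
write_phase_series <- function(phases, path) {
  write_series(
    data.frame(time = phases$time, phi1 = phases$phi1, phi2 = phases$phi2),
    path
  )
}

#' Serialize an inference run to tabular text
#'
#' Writes one row per block: block time, the inferred parameters, the
#' diagonal of the noise matrix and the quadrature covariance.
#'
#' @param run an `inference_run`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_run <- function(run, path) {
  cm <- coef_matrix(run)
  tt <- run$model$terms
  nm <- paste0(
    rep(c("c1_", "c2_"), each = run$model$n_basis),
    rep(ifelse(tt$type == "const", "const",
               paste0(tt$type, "_", tt$k, "_", tt$s)), 2)
  )
  colnames(cm) <- nm
  E <- t(sapply(run$states, function(s) diag(s$E)))
  df <- data.frame(time = run$block_times, cm,
                   E11 = E[, 1], E22 = E[, 2], q_sigma = run$q_sigma,
                   check.names = FALSE)
  write_series(df, path)
}
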