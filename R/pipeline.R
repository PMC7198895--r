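#' Configuration of an end-to-end analysis run
#'
#' Collects every setting of the simulate -> extract -> optimize ->
#' couplings workflow. The configuration round-trips losslessly through its
#' JSON text representation ([write_run_config()], [read_run_config()]).
#'
#' @param out_dir directory for the produced artifacts.
#' @param kind fixture kind (see [make_fixture()]); ignored when `input`
#'   is given.
#' @param input optional path to an existing signal table (time, sig1,
#'   sig2); when `NULL` a fixture is generated.
#' @param duration,fs fixture length (s) and sampling rate (Hz).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param band1,band2 filter bands as `c(low, high)` Hz for the two
#'   channels.
#' @param initial_t_w optional first-pass window (s); `NULL` lets the
#'   optimizer scan for the smallest feasible one.
#' @param K Fourier order of the phase model.
#' @return a `run_config` object.
#' @export
run_config <- function(out_dir,
                       kind = "sine",
                       input = NULL,
                       duration = 1800, fs = 10, seed = 1L,
                       band1 = c(0.145, 0.6), band2 = c(0.6, 2),
                       initial_t_w = NULL, K = 2) {
  structure(
    list(out_dir = out_dir, kind = kind, input = input,
         duration = duration, fs = fs, seed = as.integer(seed),
         band1 = band1, band2 = band2,
         initial_t_w = initial_t_w, K = K),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

# write through a temp file in the same directory, so a failed stage never
# leaves a partially overwritten artifact
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full adaptive-window analysis workflow
#'
#' Simulates (or reads) a raw signal pair, extracts invariant phases,
#' determines the optimal time window and propagation parameter by the
#' two-pass algorithm, runs the optimized inference, and computes the
#' time-resolved coupling measures. All artifacts are written under
#' `config$out_dir`:
#' \describe{
#'   \item{signals.tsv / signals_truth.tsv}{fixture signal pair and ground
#'     truth (only when simulating),}
#'   \item{phases.tsv}{extracted phase table,}
#'   \item{plan.txt}{key-value summary of the window plan,}
#'   \item{run.tsv}{per-block parameters, noise and quadrature covariance,}
#'   \item{couplings.tsv}{per-block coupling strength and similarity,}
#'   \item{log.json}{seeds, plan values and per-stage timings.}
#' }
#' The run is deterministic for a fixed config and seed.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress to stderr.
#' @return (invisibly) list with the plan, the optimized run, the coupling
#'   table and the artifact paths.
#' @export
pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[dbiwin] ", ...)
  log <- list(seed = config$seed, stages = list())
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  # -- signals ---------------------------------------------------------
  t0 <- tic()
  if (is.null(config$input)) {
    say("simulating '", config$kind, "' fixture")
    fx <- make_fixture(config$kind, duration = config$duration,
                       fs = config$fs, seed = config$seed,
                       path = file.path(config$out_dir, "signals"))
    sig <- data.frame(time = fx$time, sig1 = fx$sig1, sig2 = fx$sig2)
  } else {
    say("reading ", config$input)
    sig <- read_series(config$input)
    if (ncol(sig) < 3) stop("input needs columns time, sig1, sig2")
    names(sig)[2:3] <- c("sig1", "sig2")
  }
  log$stages$signals <- toc(t0)

  # -- phases ----------------------------------------------------------
  t0 <- tic()
  say("extracting phases")
  fs <- 1 / stats::median(diff(sig$time))
  phases <- extract_phases(
    sig$time, sig$sig1, sig$sig2,
    band_spec(config$band1[1], config$band1[2], fs),
    band_spec(config$band2[1], config$band2[2], fs)
  )
  phase_path <- file.path(config$out_dir, "phases.tsv")
  write_atomic(function(p) write_phase_series(phases, p), phase_path)
  log$stages$phases <- toc(t0)

  # -- window optimization + inference ---------------------------------
  t0 <- tic()
  say("optimizing time window")
  opt <- optimize_inference(phases, initial_t_w = config$initial_t_w,
                            K = config$K)
  plan_path <- file.path(config$out_dir, "plan.txt")
  write_atomic(function(p) {
    writeLines(c(
      paste0("f_max\t", format(opt$plan$f_max, digits = 10)),
      paste0("T_min\t", format(opt$plan$T_min, digits = 10)),
      paste0("t_w_opt\t", format(opt$plan$t_w_opt, digits = 10)),
      paste0("p_w_opt\t", format(opt$plan$p_w_opt, digits = 10)),
      paste0("initial_t_w\t", format(opt$plan$initial_t_w, digits = 10))
    ), p)
  }, plan_path)
  run_path <- file.path(config$out_dir, "run.tsv")
  write_atomic(function(p) write_run(opt$run, p), run_path)
  log$stages$optimize <- toc(t0)
  log$plan <- opt$plan[c("f_max", "t_w_opt", "p_w_opt", "initial_t_w")]

  # -- couplings -------------------------------------------------------
  t0 <- tic()
  say("computing coupling measures")
  cpl <- time_resolved_similarity(opt$run)
  cpl_path <- file.path(config$out_dir, "couplings.tsv")
  write_atomic(function(p) write_series(cpl, p), cpl_path)
  log$stages$couplings <- toc(t0)

  log_path <- file.path(config$out_dir, "log.json")
  write_atomic(function(p) {
    jsonlite::write_json(log, p, auto_unbox = TRUE, digits = NA)
  }, log_path)
  say("done")
  invisible(list(
    plan = opt$plan, run = opt$run, couplings = cpl,
    paths = c(phases = phase_path, plan = plan_path, run = run_path,
              couplings = cpl_path, log = log_path)
  ))
}
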