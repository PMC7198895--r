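# Shared simulations, computed lazily and cached for the whole test run.
# The default study conditions: cardiorespiratory-scale coupled phase
# oscillators, 2000 s at h = 0.01, moderate noise.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

study_sim <- function() {
  memo("study_sim", simulate_phase_pair(phase_pair_config(seed = 1)))
}

# optimized two-pass result on the study simulation
study_opt <- function() {
  memo("study_opt", optimize_inference(study_sim()))
}

poincare_sim <- function() {
  memo("poincare_sim",
       simulate_poincare_pair(poincare_config(duration = 1000, seed = 2)))
}

# a fake inference run with a prescribed block-parameter matrix, for
# operations that only consume the block series
fake_run <- function(cm, t_w = 10, K = 2) {
  states <- lapply(seq_len(nrow(cm)), function(b) {
    structure(list(c = cm[b, ], E = diag(2),
                   Sigma = diag(1e-4, length(cm[b, ])),
                   block_time = (b - 0.5) * t_w, converged = TRUE),
              class = "model_state")
  })
  structure(
    list(states = states,
         q_sigma = rep(1, nrow(cm)),
         block_times = (seq_len(nrow(cm)) - 0.5) * t_w,
         settings = inference_settings(t_w = t_w, p_w = 0.2, K = K),
         model = fourier_model(K), h = 0.01),
    class = "inference_run"
  )
}
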