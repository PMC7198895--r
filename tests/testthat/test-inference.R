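# build a state by hand for operations that only read c / Sigma / E
manual_state <- function(c, Sigma = diag(length(c)), E = diag(2)) {
  structure(list(c = c, E = E, Xi = solve(Sigma), Sigma = Sigma,
                 block_time = NA_real_, converged = TRUE),
            class = "model_state")
}

test_that("basis layout: constant column, zero-phase values, index lookup", {
  m <- fourier_model(2)
  expect_equal(m$n_basis, 25)
  eb <- evaluate_basis(c(0, 1, 2), c(0, 0.5, 1), m)
  expect_equal(eb$Phi[, 1], rep(1, 3))

  m1 <- fourier_model(1)
  eb1 <- evaluate_basis(0, 0, m1)
  sin_cols <- which(m1$terms$type == "sin")
  cos_cols <- which(m1$terms$type == "cos")
  expect_equal(as.vector(eb1$Phi[, sin_cols]), rep(0, length(sin_cols)))
  expect_equal(as.vector(eb1$Phi[, cos_cols]), rep(1, length(cos_cols)))

  expect_equal(basis_index(m, 1, 0, 0, "const"), 1)
  expect_equal(basis_index(m, 2, 0, 0, "const"), 26)
  expect_error(basis_index(m, 1, 3, 0, "sin"), "no such")
})

test_that("basis derivatives agree with finite differences", {
  m <- fourier_model(2)
  set.seed(1)
  p1 <- stats::runif(20, 0, 2 * pi)
  p2 <- stats::runif(20, 0, 2 * pi)
  eb <- evaluate_basis(p1, p2, m)
  eps <- 1e-6
  fd1 <- (evaluate_basis(p1 + eps, p2, m)$Phi -
          evaluate_basis(p1 - eps, p2, m)$Phi) / (2 * eps)
  fd2 <- (evaluate_basis(p1, p2 + eps, m)$Phi -
          evaluate_basis(p1, p2 - eps, m)$Phi) / (2 * eps)
  expect_lt(max(abs(fd1 - eb$dPhi1)), 1e-6)
  expect_lt(max(abs(fd2 - eb$dPhi2)), 1e-6)
})

test_that("flat-prior zero-noise update equals ordinary least squares", {
  set.seed(7)
  m1 <- fourier_model(1)
  ctrue <- c(2.0, 0.3, 0, 0.2, 0, -0.1, 0, 0, 0.15,
             5.0, 0, 0, 0, 0.1, 0, 0.3, 0, 0)
  h <- 0.01
  n <- 3000
  phi1 <- numeric(n + 1); phi2 <- numeric(n + 1); phi2[1] <- 1
  for (i in 1:n) {
    eb <- evaluate_basis(phi1[i], phi2[i], m1)
    d <- as.vector(eb$Phi %*% matrix(ctrue, 9, 2))
    phi1[i + 1] <- phi1[i] + h * d[1]
    phi2[i + 1] <- phi2[i] + h * d[2]
  }
  st <- infer_block(list(phi1 = phi1, phi2 = phi2, h = h),
                    settings = inference_settings(t_w = 30, p_w = 0.2, K = 1))
  mid1 <- (phi1[-1] + phi1[-(n + 1)]) / 2
  mid2 <- (phi2[-1] + phi2[-(n + 1)]) / 2
  X <- evaluate_basis(mid1, mid2, m1)$Phi
  ols <- c(stats::lm.fit(X, diff(phi1) / h)$coefficients,
           stats::lm.fit(X, diff(phi2) / h)$coefficients)
  expect_lt(max(abs(st$c - ols)), 1e-8)
  expect_lt(max(abs(st$c - ctrue)), 0.05)
})

test_that("an effectively frozen prior pins the posterior mean", {
  ps <- study_sim()
  idx <- 1:501
  blk <- list(phi1 = ps$phi1[idx], phi2 = ps$phi2[idx], h = ps$h)
  m <- fourier_model(2)
  c0 <- seq_len(50) / 10
  prior <- manual_state(c0, Sigma = diag(1e-12, 50))
  st <- infer_block(blk, prior, inference_settings(t_w = 5, p_w = 0.2))
  expect_equal(st$c, c0, tolerance = 1e-4)
})

test_that("diffusion propagation widens the covariance by (p_w c)^2", {
  st <- manual_state(c(1, 2), Sigma = diag(0.01, 2))
  pr <- propagate_prior(st, inference_settings(t_w = 5, p_w = 0.2))
  expect_equal(diag(pr$Sigma), c(0.01 + 0.04, 0.01 + 0.16))
  expect_equal(pr$c, st$c)
  expect_equal(pr$Xi %*% pr$Sigma, diag(2), tolerance = 1e-12)

  pr0 <- propagate_prior(st, inference_settings(t_w = 5, p_w = 0))
  expect_equal(pr0$Sigma, st$Sigma)

  stz <- manual_state(c(0, 2), Sigma = diag(0.01, 2))
  prz <- propagate_prior(stz, inference_settings(t_w = 5, p_w = 0.2))
  expect_equal(prz$Sigma[1, 1], 0.01)  # zero parameter diffuses nothing
})

test_that("quadrature covariance has its closed-form values", {
  expect_equal(quadrature_covariance(matrix(0, 3, 3)), 0)
  expect_equal(quadrature_covariance(diag(4)), 4)
  expect_equal(quadrature_covariance(diag(c(0.1, 0.2))), 0.05)
})

test_that("stationary system yields flat parameter tracks and tight noise recovery", {
  cfg <- phase_pair_config(omega1_mod = 0, a3_mod = 0, duration = 600,
                           seed = 9)
  ps <- simulate_phase_pair(cfg)
  run <- run_sequential(ps, inference_settings(t_w = 50, p_w = 0.2))
  m <- fourier_model(2)
  cm <- coef_matrix(run)[-(1:2), ]
  iw2 <- basis_index(m, 2, 0, 0, "const")
  expect_equal(mean(cm[, iw2]), cfg$omega2, tolerance = 0.01)
  expect_lt(stats::sd(cm[, iw2]), 0.05)
  ia1 <- basis_index(m, 1, 1, 0, "sin")
  expect_equal(mean(cm[, ia1]), cfg$a1, tolerance = 0.1)
  # noise amplitudes: sqrt of the inferred intensity within 10 percent
  Ehat <- sqrt(t(sapply(run$states[-(1:2)], function(s) diag(s$E))))
  expect_equal(mean(Ehat[, 1]), cfg$E11, tolerance = 0.1)
  expect_equal(mean(Ehat[, 2]), cfg$E22, tolerance = 0.1)
})

test_that("posterior covariance tightens with longer stationary blocks", {
  cfg <- phase_pair_config(omega1_mod = 0, a3_mod = 0, duration = 400,
                           seed = 10)
  ps <- simulate_phase_pair(cfg)
  s10 <- run_sequential(ps, inference_settings(t_w = 10, p_w = 0.2))
  s40 <- run_sequential(ps, inference_settings(t_w = 40, p_w = 0.2))
  d10 <- mean(sapply(s10$states[-(1:2)], function(s) mean(diag(s$Sigma))))
  d40 <- mean(sapply(s40$states[-(1:2)], function(s) mean(diag(s$Sigma))))
  expect_lt(d40, d10)
})

test_that("relabelling the oscillators permutes the inferred parameters", {
  ps <- study_sim()
  short <- phase_pair_series(ps$time[1:20001], ps$phi1[1:20001],
                             ps$phi2[1:20001], ps$h)
  swapped <- phase_pair_series(ps$time[1:20001], ps$phi2[1:20001],
                               ps$phi1[1:20001], ps$h)
  set <- inference_settings(t_w = 50, p_w = 0.2)
  ra <- run_sequential(short, set)
  rb <- run_sequential(swapped, set)
  m <- fourier_model(2)
  ca <- colMeans(coef_matrix(ra)[-(1:2), ])
  cb <- colMeans(coef_matrix(rb)[-(1:2), ])
  # natural frequencies swap places
  expect_equal(ca[basis_index(m, 1, 0, 0, "const")],
               cb[basis_index(m, 2, 0, 0, "const")], tolerance = 0.02)
  expect_equal(ca[basis_index(m, 2, 0, 0, "const")],
               cb[basis_index(m, 1, 0, 0, "const")], tolerance = 0.02)
  # self term of oscillator 2 (a4 sin(phi2)) appears as the k/s-swapped
  # self term of dimension 1 in the relabelled run
  expect_equal(ca[basis_index(m, 2, 0, 1, "sin")],
               cb[basis_index(m, 1, 1, 0, "sin")], tolerance = 0.1)
})

test_that("time-varying frequency is recovered on the study system", {
  opt <- study_opt()
  m <- fourier_model(2)
  cfg <- phase_pair_config()
  cm <- coef_matrix(opt$run)[-(1:2), ]
  # mean of omega1(t) equals omega1_const; omega2 is constant
  expect_equal(mean(cm[, basis_index(m, 1, 0, 0, "const")]),
               cfg$omega1_const, tolerance = 0.02)
  expect_equal(mean(cm[, basis_index(m, 2, 0, 0, "const")]),
               cfg$omega2, tolerance = 0.01)
})

test_that("blocks below the information floor raise a singular-matrix error", {
  ps <- study_sim()
  expect_error(
    infer_block(list(phi1 = ps$phi1[1:50], phi2 = ps$phi2[1:50], h = ps$h),
                settings = inference_settings(t_w = 0.5, p_w = 0.2)),
    class = "dbiwin_singular"
  )
  err <- tryCatch(
    run_sequential(ps, inference_settings(t_w = 0.6, p_w = 0.2)),
    error = function(e) e
  )
  expect_s3_class(err, "dbiwin_singular")
  expect_match(conditionMessage(err), "block 1")
})
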