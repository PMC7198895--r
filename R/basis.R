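#' Fourier basis for two-oscillator phase dynamics
#'
#' The phase velocity of each oscillator is modelled as a truncated Fourier
#' series in the two phases,
#' \deqn{\dot\phi_i = \sum_k c^i_k \Phi_k(\phi_1, \phi_2) + \xi_i(t),}
#' with a shared set of real base functions: a constant (whose coefficient is
#' the natural frequency \eqn{\omega_i}) followed by sine/cosine pairs of the
#' combination angles \eqn{k\phi_1 + s\phi_2}.
#'
#' The ordering is fixed and shared by every routine in the package:
#' the constant first, then the pairs \eqn{(k, s)} with \eqn{k = 0, s = 1..K}
#' and \eqn{k = 1..K, s = -K..K}, in increasing \eqn{(k, s)} order, each
#' contributing `sin` before `cos`. Pairs with \eqn{k < 0} are redundant
#' (differ only in sign) and are excluded. For `K = 2` this gives 25 base
#' functions per oscillator, 50 model parameters in total.
#'
#' @param K Fourier order (number of harmonics retained per phase); default 2.
#' @return an object of class `fourier_model` with elements
#'   \item{K}{the order,}
#'   \item{terms}{data frame describing each base function: `k`, `s`,
#'     `type` (`"const"`, `"sin"`, `"cos"`),}
#'   \item{n_basis}{number of base functions per oscillator.}
#' @export
fourier_model <- function(K = 2) {
  stopifnot(is.numeric(K), length(K) == 1, K >= 1, K == round(K))
  ks <- rbind(
    if (K >= 1) cbind(k = 0, s = seq_len(K)),
    do.call(rbind, lapply(seq_len(K), function(k) cbind(k = k, s = -K:K)))
  )
  terms <- data.frame(
    k = c(0, rep(ks[, "k"], each = 2)),
    s = c(0, rep(ks[, "s"], each = 2)),
    type = c("const", rep(c("sin", "cos"), times = nrow(ks))),
    stringsAsFactors = FALSE
  )
  structure(
    list(K = K, terms = terms, n_basis = nrow(terms)),
    class = "fourier_model"
  )
}

#' @export
print.fourier_model <- function(x, ...) {
  cat("Fourier phase model, order K =", x$K, "\n")
  cat(" ", x$n_basis, "base functions per oscillator,",
      2 * x$n_basis, "parameters in total\n")
  invisible(x)
}

#' Indices of base functions within the full parameter vector
#'
#' The parameter vector concatenates oscillator 1's coefficients followed by
#' oscillator 2's. `basis_index()` locates one base function for one
#' oscillator; `coupling_indices()` returns all cross terms, i.e. the base
#' functions that depend on the partner oscillator's phase (these form the
#' coupling function \eqn{q_i}).
#'
#' @param model a [fourier_model()].
#' @param oscillator 1 or 2: whose dynamics the coefficient belongs to.
#' @param k,s harmonic numbers of the combination angle `k*phi1 + s*phi2`.
#' @param type `"const"`, `"sin"` or `"cos"`.
#' @return integer index (or indices) into the length-`2*n_basis` parameter
#'   vector.
#' @export
basis_index <- function(model, oscillator, k, s, type) {
  stopifnot(inherits(model, "fourier_model"), oscillator %in% c(1, 2))
  i <- which(model$terms$k == k & model$terms$s == s & model$terms$type == type)
  if (length(i) != 1) {
    stop("no such base function: k=", k, ", s=", s, ", type=", type)
  }
  (oscillator - 1) * model$n_basis + i
}

#' @rdname basis_index
#' @export
coupling_indices <- function(model, oscillator) {
  stopifnot(inherits(model, "fourier_model"), oscillator %in% c(1, 2))
  # oscillator 1 is influenced through phi2 (s != 0), oscillator 2 through
  # phi1 (k != 0); constant and pure self terms are excluded
  dep <- if (oscillator == 1) model$terms$s != 0 else model$terms$k != 0
  (oscillator - 1) * model$n_basis + which(dep)
}

#' Evaluate the Fourier basis and its phase derivatives
#'
#' Evaluates every base function, and its partial derivatives with respect to
#' each phase, at the supplied phase pairs. Phases may be wrapped or
#' unwrapped; the basis is 2*pi-periodic in both arguments.
#'
#' @param phi1,phi2 numeric vectors of equal length, phases in radians.
#' @param model a [fourier_model()].
#' @return list with `Phi` (n x n_basis design matrix), `dPhi1`, `dPhi2`
#'   (matrices of the derivatives with respect to `phi1` and `phi2`), columns
#'   ordered as `model$terms`.
#' @export
evaluate_basis <- function(phi1, phi2, model = fourier_model()) {
  if (length(phi1) != length(phi2)) {
    stop("phi1 and phi2 must have the same length")
  }
  n <- length(phi1)
  tt <- model$terms
  F <- model$n_basis
  Phi <- matrix(0, n, F)
  dPhi1 <- matrix(0, n, F)
  dPhi2 <- matrix(0, n, F)
  Phi[, 1] <- 1
  j <- 2
  while (j <= F) {
    k <- tt$k[j]; s <- tt$s[j]
    arg <- k * phi1 + s * phi2
    sa <- sin(arg); ca <- cos(arg)
    # sin column at j, cos column at j + 1 (construction of fourier_model)
    Phi[, j] <- sa
    dPhi1[, j] <- k * ca
    dPhi2[, j] <- s * ca
    Phi[, j + 1] <- ca
    dPhi1[, j + 1] <- -k * sa
    dPhi2[, j + 1] <- -s * sa
    j <- j + 2
  }
  list(Phi = Phi, dPhi1 = dPhi1, dPhi2 = dPhi2)
}
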