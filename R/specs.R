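#' Network specification
#'
#' An architecture-agnostic description of a recurrent rate network:
#' unit counts, signed weight matrix, membrane time constants, resting
#' potential, nonlinearity, and (for ring models) preferred angles.
#'
#' Voltage dynamics are
#' `tau_i dV_i/dt = -V_i + Vrest + h_i(t) + eta_i(t) + sum_j W_ij r(V_j)`,
#' with `W` carrying the signs (columns from inhibitory units are
#' non-positive when Dale's law holds).
#'
#' @param N_E,N_I numbers of excitatory and inhibitory units. Models
#'   without an E/I distinction use `N_E = N`, `N_I = 0`.
#' @param W `N x N` signed weight matrix (mV s); `W[i, j]` is the
#'   connection from unit `j` onto unit `i`.
#' @param tau per-unit membrane time constants (ms); scalar or length-N.
#' @param Vrest resting potential (mV).
#' @param nl an [nonlinearity()] object.
#' @param theta optional per-unit preferred angle on the full circle
#'   (degrees, ring models only).
#' @param dale if `TRUE`, check column signs against E/I identity.
#' @return an object of class `ssn_network`.
#' @export
network_spec <- function(N_E, N_I, W, tau, Vrest = -70, nl, theta = NULL,
                         dale = FALSE) {
  N <- N_E + N_I
  W <- as.matrix(W)
  stopifnot(nrow(W) == N, ncol(W) == N, all(tau > 0))
  tau <- rep_len(tau, N)
  is_E <- c(rep(TRUE, N_E), rep(FALSE, N_I))
  if (dale) {
    if (N_E > 0 && any(W[, is_E, drop = FALSE] < 0))
      stop("Dale's law violated: negative weight from an excitatory unit")
    if (N_I > 0 && any(W[, !is_E, drop = FALSE] > 0))
      stop("Dale's law violated: positive weight from an inhibitory unit")
  }
  if (!is.null(theta)) stopifnot(length(theta) == N)
  structure(list(N_E = N_E, N_I = N_I, N = N, W = W, tau = tau,
                 Vrest = Vrest, nl = nl, theta = theta, is_E = is_E),
            class = "ssn_network")
}

#' @export
print.ssn_network <- function(x, ...) {
  cat(sprintf("<ssn_network> %d units (%d E, %d I), tau in [%g, %g] ms, Vrest = %g mV\n",
              x$N, x$N_E, x$N_I, min(x$tau), max(x$tau), x$Vrest))
  print(x$nl)
  if (!is.null(x$theta)) cat("ring geometry: angles on [0, 360) deg\n")
  invisible(x)
}

#' Input-noise specification
#'
#' Parameters of the multivariate Ornstein-Uhlenbeck (OU) input noise
#' `tau_noise * d eta = -eta dt + sqrt(2 tau_noise Sigma) d xi`,
#' whose stationary law is `eta ~ N(0, Sigma)` with autocovariance
#' `Sigma_ij exp(-|lag| / tau_noise)`.
#'
#' @param tau_noise noise correlation time (ms).
#' @param Sigma `N x N` symmetric positive semidefinite covariance (mV^2).
#' @param factor optional precomputed square-root factor `L` with
#'   `L %*% t(L) == Sigma` (used to avoid an eigendecomposition when the
#'   covariance has known structure).
#' @param tol eigenvalues below `-tol` raise an invalid-covariance error;
#'   eigenvalues in `[-tol, 0)` are clipped to zero.
#' @return an object of class `ssn_noise`.
#' @export
noise_spec <- function(tau_noise, Sigma, factor = NULL, tol = 1e-10) {
  stopifnot(tau_noise > 0)
  Sigma <- as.matrix(Sigma)
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * (1 + max(abs(Sigma))))
    stop("Sigma must be symmetric")
  Sigma <- (Sigma + t(Sigma)) / 2
  structure(list(tau_noise = tau_noise, Sigma = Sigma, factor = factor,
                 tol = tol),
            class = "ssn_noise")
}

#' @export
print.ssn_noise <- function(x, ...) {
  cat(sprintf("<ssn_noise> N = %d, tau_noise = %g ms, tr(Sigma) = %g mV^2\n",
              nrow(x$Sigma), x$tau_noise, sum(diag(x$Sigma))))
  invisible(x)
}

# Symmetric square-root factor of Sigma; clips small negative eigenvalues.
noise_factor <- function(noise) {
  if (!is.null(noise$factor)) return(noise$factor)
  eg <- eigen(noise$Sigma, symmetric = TRUE)
  if (min(eg$values) < -noise$tol)
    stop(sprintf("invalid covariance: eigenvalue %g < -tol", min(eg$values)))
  lam <- pmax(eg$values, 0)
  eg$vectors %*% (sqrt(lam) * t(eg$vectors))
}

#' Piecewise-constant stimulus protocol
#'
#' A stimulus protocol is a sequence of segments, each holding a constant
#' mean-input vector `h` (mV) for a given duration (ms).
#'
#' @param durations segment durations (ms), all positive.
#' @param h a list of input vectors (one per segment) or a matrix with one
#'   column per segment; scalars are recycled across units at simulation
#'   time.
#' @param contrast optional per-segment contrast scalar (metadata).
#' @return an object of class `ssn_protocol`.
#' @examples
#' # 1 s at h = 2 mV, then 500 ms at 15 mV, then 1 s back at 2 mV
#' stimulus_protocol(c(1000, 500, 1000), list(2, 15, 2))
#' @export
stimulus_protocol <- function(durations, h, contrast = NULL) {
  stopifnot(all(durations > 0))
  if (is.matrix(h)) h <- lapply(seq_len(ncol(h)), function(j) h[, j])
  if (!is.list(h)) h <- as.list(h)
  stopifnot(length(h) == length(durations))
  structure(list(durations = durations, h = h, contrast = contrast,
                 total = sum(durations)),
            class = "ssn_protocol")
}

#' @export
print.ssn_protocol <- function(x, ...) {
  cat(sprintf("<ssn_protocol> %d segment(s), total %g ms\n",
              length(x$durations), x$total))
  invisible(x)
}

# Expand protocol to per-segment (n_steps, h vector of length N) given dt.
protocol_segments <- function(protocol, N, dt) {
  n_steps <- round(protocol$durations / dt)
  if (any(n_steps < 1)) stop("protocol segment shorter than one time step")
  hs <- lapply(protocol$h, function(h) {
    if (length(h) == 1) rep(h, N) else {
      stopifnot(length(h) == N)
      as.numeric(h)
    }
  })
  list(n_steps = n_steps, h = hs)
}
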