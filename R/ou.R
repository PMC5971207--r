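#' Sample a multivariate Ornstein-Uhlenbeck noise trajectory
#'
#' Draws a stationary trajectory of the OU input-noise process. The
#' update is exact per step (exponential propagator), so the stationary
#' law `eta ~ N(0, Sigma)` with autocovariance
#' `Sigma_ij exp(-|lag|/tau_noise)` holds at any step size; the initial
#' state is drawn from the stationary distribution.
#'
#' @param noise an [noise_spec()] object.
#' @param duration trajectory length (ms).
#' @param dt time step (ms).
#' @param seed integer seed.
#' @return a `n_steps x N` matrix (mV); rows are successive time steps.
#' @export
sample_ou_noise <- function(noise, duration, dt, seed = 1L) {
  set.seed(seed)
  L <- noise_factor(noise)
  N <- nrow(L)
  n_steps <- round(duration / dt)
  a <- exp(-dt / noise$tau_noise)
  b <- sqrt(1 - a^2)
  out <- matrix(0, n_steps, N)
  eta <- drop(L %*% stats::rnorm(N))
  for (s in seq_len(n_steps)) {
    out[s, ] <- eta
    eta <- a * eta + b * drop(L %*% stats::rnorm(N))
  }
  out
}

# One exact OU update for an N x n_trials state matrix.
ou_step <- function(eta, L, a, b) {
  a * eta + b * (L %*% matrix(stats::rnorm(length(eta)), nrow(eta)))
}
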