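#' Integrate stochastic rate-network dynamics
#'
#' Forward-Euler integration (default step 0.1 ms) of
#' `tau_i dV_i/dt = -V_i + Vrest + h_i(t) + eta_i(t) + sum_j W_ij r(V_j)`
#' for `n_trials` independent trials. The Ornstein-Uhlenbeck input noise
#' is advanced with its exact exponential propagator, so its stationary
#' law is correct at any `dt`. Trials are integrated jointly (the state is
#' an `N x n_trials` matrix); all randomness derives from `seed`, with the
#' per-step innovations for all trials drawn from a single stream in
#' column-major (unit-within-trial) order, so a run is bit-reproducible
#' given `(seed, dt, n_trials)`.
#'
#' @param net an [network_spec()] object.
#' @param protocol an [stimulus_protocol()] object.
#' @param noise an [noise_spec()] object, or `NULL` for deterministic
#'   dynamics (e.g. the chaotic network).
#' @param dt Euler time step (ms); must satisfy `dt <= 0.1 * min(tau)`.
#' @param seed integer seed.
#' @param n_trials number of independent trials.
#' @param record which per-step summaries to store: any of `"V"`
#'   (membrane potentials), `"r"` (rates), `"trial_stats"` (across-trial
#'   mean and variance of V per neuron, stored without keeping trials).
#' @param record_dt recording resolution (ms); must be a multiple of `dt`.
#' @param rate_bin_ms if non-`NULL`, accumulate the expected spike count
#'   `integral r dt` per neuron, trial and time bin of this width (used
#'   for doubly stochastic Poisson counts).
#' @param V_init initial condition: `"rest"` (all at `Vrest`), `"random"`
#'   (`Vrest + init_sd * N(0,1)` per unit and trial), or a numeric vector
#'   or `N x n_trials` matrix.
#' @param init_sd standard deviation (mV) for `V_init = "random"`.
#' @param guard instability guard (mV): integration aborts with an error
#'   naming the first offending step if any `|V|` exceeds it.
#' @return an object of class `ssn_sim` with elements `times` (ms),
#'   `V` and `r` (`n_rec x N x n_trials` arrays, if recorded),
#'   `trial_mean` / `trial_var` (`n_rec x N`, if recorded), `lambda`
#'   (`n_bins x N x n_trials` expected counts per bin, if requested),
#'   `bin_times`, and the simulation metadata.
#' @export
integrate_network <- function(net, protocol, noise = NULL, dt = 0.1,
                              seed = 1L, n_trials = 1L,
                              record = "V", record_dt = 1,
                              rate_bin_ms = NULL,
                              V_init = "rest", init_sd = 1,
                              guard = 1000) {
  if (dt > 0.1 * min(net$tau) + 1e-12)
    stop("dt must satisfy dt <= 0.1 * min(tau)")
  seg <- protocol_segments(protocol, net$N, dt)
  n_tot <- sum(seg$n_steps)
  rec_every <- round(record_dt / dt)
  if (abs(rec_every * dt - record_dt) > 1e-9)
    stop("record_dt must be a multiple of dt")
  n_rec <- n_tot %/% rec_every
  N <- net$N

  set.seed(seed)
  # initial state
  if (is.character(V_init)) {
    V <- switch(V_init,
      rest   = matrix(net$Vrest, N, n_trials),
      random = matrix(net$Vrest + init_sd * stats::rnorm(N * n_trials), N, n_trials),
      stop("unknown V_init: ", V_init))
  } else {
    V <- if (is.matrix(V_init)) V_init else matrix(V_init, N, n_trials)
    stopifnot(nrow(V) == N, ncol(V) == n_trials)
  }

  has_noise <- !is.null(noise)
  if (has_noise) {
    L <- noise_factor(noise)
    a_ou <- exp(-dt / noise$tau_noise)
    b_ou <- sqrt(1 - a_ou^2)
    eta <- L %*% matrix(stats::rnorm(N * n_trials), N)
  }

  rec_V  <- "V" %in% record
  rec_r  <- "r" %in% record
  rec_ts <- "trial_stats" %in% record
  V_arr <- if (rec_V) array(NA_real_, c(n_rec, N, n_trials)) else NULL
  r_arr <- if (rec_r) array(NA_real_, c(n_rec, N, n_trials)) else NULL
  tmean <- if (rec_ts) matrix(NA_real_, n_rec, N) else NULL
  tvar  <- if (rec_ts) matrix(NA_real_, n_rec, N) else NULL

  do_bins <- !is.null(rate_bin_ms)
  if (do_bins) {
    bin_steps <- round(rate_bin_ms / dt)
    n_bins <- n_tot %/% bin_steps
    lambda <- array(0, c(n_bins, N, n_trials))
    acc <- matrix(0, N, n_trials)
    bin_idx <- 1L
  }

  dt_tau <- dt / net$tau        # length N, recycles down columns
  vcorr <- if (n_trials > 1) n_trials / (n_trials - 1) else 1
  step <- 0L
  rec_idx <- 0L
  for (s_i in seq_along(seg$n_steps)) {
    h <- seg$h[[s_i]]
    for (k in seq_len(seg$n_steps[[s_i]])) {
      step <- step + 1L
      r <- eval_nonlinearity(net$nl, V)
      drive <- net$W %*% r
      if (has_noise) {
        V <- V + dt_tau * ((net$Vrest - V) + h + eta + drive)
        eta <- a_ou * eta + b_ou * (L %*% matrix(stats::rnorm(N * n_trials), N))
      } else {
        V <- V + dt_tau * ((net$Vrest - V) + h + drive)
      }
      if (max(abs(V)) > guard)
        stop(sprintf("instability: |V| exceeded %g mV at step %d (t = %g ms)",
                     guard, step, step * dt))
      if (do_bins) {
        acc <- acc + r * (dt / 1000)   # expected counts (r in 1/s, dt in ms)
        if (step %% bin_steps == 0L && bin_idx <= n_bins) {
          lambda[bin_idx, , ] <- acc
          acc[] <- 0
          bin_idx <- bin_idx + 1L
        }
      }
      if (step %% rec_every == 0L) {
        rec_idx <- rec_idx + 1L
        if (rec_V) V_arr[rec_idx, , ] <- V
        if (rec_r) r_arr[rec_idx, , ] <- eval_nonlinearity(net$nl, V)
        if (rec_ts) {
          m <- rowMeans(V)
          tmean[rec_idx, ] <- m
          tvar[rec_idx, ]  <- (rowMeans(V * V) - m * m) * vcorr
        }
      }
    }
  }

  out <- list(net = net, protocol = protocol, noise = noise, dt = dt,
              seed = seed, n_trials = n_trials, record_dt = record_dt,
              times = seq_len(n_rec) * record_dt,
              V = V_arr, r = r_arr, trial_mean = tmean, trial_var = tvar,
              lambda = if (do_bins) lambda else NULL,
              bin_ms = if (do_bins) rate_bin_ms else NULL,
              bin_times = if (do_bins) seq_len(n_bins) * rate_bin_ms else NULL)
  class(out) <- "ssn_sim"
  out
}

#' @export
print.ssn_sim <- function(x, ...) {
  cat(sprintf("<ssn_sim> %d units, %d trial(s), %g ms simulated (dt = %g ms, seed = %d)\n",
              x$net$N, x$n_trials, x$protocol$total, x$dt, x$seed))
  stored <- c(if (!is.null(x$V)) "V", if (!is.null(x$r)) "r",
              if (!is.null(x$trial_var)) "trial stats",
              if (!is.null(x$lambda)) sprintf("rate integrals (%g ms bins)", x$bin_ms))
  cat("stored:", paste(stored, collapse = ", "), "\n")
  invisible(x)
}

#' Find a fixed point of the noiseless dynamics
#'
#' Solves `0 = -V + Vrest + h + W r(V)` by relaxation (noiseless
#' integration with a large stable step) or damped Newton iteration. The
#' Jacobian of the dynamics at the solution is checked; if any eigenvalue
#' has non-negative real part a `stable = FALSE` attribute is set with a
#' warning.
#'
#' @param net an [network_spec()] object.
#' @param h mean input (mV); scalar or length-N vector.
#' @param method `"relaxation"` (default) or `"newton"`.
#' @param tol convergence tolerance on the residual infinity norm (mV).
#' @param max_iter maximum iterations.
#' @return the fixed-point voltage vector (mV), with attributes
#'   `residual`, `stable`, and `jacobian_eigenvalues`.
#' @export
fixed_point <- function(net, h, method = c("relaxation", "newton"),
                        tol = 1e-8, max_iter = 100000L) {
  method <- match.arg(method)
  h <- if (length(h) == 1) rep(h, net$N) else h
  stopifnot(length(h) == net$N)
  resid <- function(V) -V + net$Vrest + h + drop(net$W %*% eval_nonlinearity(net$nl, V))
  V <- net$Vrest + h
  if (method == "relaxation") {
    step <- 0.5 * min(net$tau) / net$tau   # per-unit Euler factor, stable
    for (it in seq_len(max_iter)) {
      FV <- resid(V)
      if (max(abs(FV)) < tol) break
      V <- V + step * FV
    }
    if (max(abs(resid(V))) >= tol)
      stop("fixed_point: relaxation did not converge (no stable fixed point?)")
  } else {
    FV <- resid(V)
    for (it in seq_len(max_iter)) {
      if (max(abs(FV)) < tol) break
      J <- -diag(net$N) + sweep(net$W, 2, nl_derivative(net$nl, V), "*")
      dV <- tryCatch(-solve(J, FV), error = function(e)
        stop("fixed_point: singular Jacobian in Newton iteration"))
      lam <- 1
      repeat {
        Vn <- V + lam * dV
        Fn <- resid(Vn)
        if (max(abs(Fn)) < max(abs(FV)) || lam < 1e-6) break
        lam <- lam / 2
      }
      if (lam < 1e-6) stop("fixed_point: Newton line search failed")
      V <- Vn; FV <- Fn
      if (it == max_iter) stop("fixed_point: Newton did not converge")
    }
  }
  A <- jacobian_at(net, V)
  ev <- eigen(A, only.values = TRUE)$values
  stable <- max(Re(ev)) < 0
  if (!stable) warning("fixed point is linearly unstable")
  structure(V, residual = max(abs(resid(V))), stable = stable,
            jacobian_eigenvalues = ev)
}

# Jacobian of dV/dt at V: diag(1/tau) (W_eff - I), in 1/ms.
jacobian_at <- function(net, V) {
  Weff <- effective_weights(net, V)
  sweep(Weff - diag(net$N), 1, net$tau, "/")
}

#' Effective (linearized) connection weights
#'
#' `W_eff[i, j] = W[i, j] * f'(Vbar[j])`: the anatomical weights scaled by
#' the slope of the firing-rate nonlinearity at the operating point. For
#' the supralinear power law the slope, and hence the effective
#' connectivity, grows with the mean input.
#'
#' @param net an [network_spec()] object.
#' @param Vbar operating-point voltages, typically from [fixed_point()].
#' @return the `N x N` effective weight matrix (dimensionless).
#' @export
effective_weights <- function(net, Vbar) {
  sweep(net$W, 2, nl_derivative(net$nl, as.numeric(Vbar)), "*")
}

#' Stationary covariance of linearized fluctuations
#'
#' Covariance of small voltage fluctuations `dV` around the stable fixed
#' point, under the linearized dynamics
#' `tau dV/dt = (W_eff - I) dV + eta` with OU input noise. The joint
#' stationary covariance of `(dV, eta)` solves a continuous Lyapunov
#' equation on the augmented state; the block structure is exploited: the
#' noise block is `Sigma` exactly, the cross block is a linear solve, and
#' the voltage block solves an `N x N` Lyapunov equation via the
#' eigendecomposition of the Jacobian.
#'
#' @param net an [network_spec()] object.
#' @param noise an [noise_spec()] object.
#' @param h mean input (mV); scalar or length-N.
#' @param Vbar optional precomputed fixed point.
#' @return the `N x N` stationary covariance of `dV` (mV^2), with
#'   attribute `Vbar`.
#' @export
linearized_covariance <- function(net, noise, h, Vbar = NULL) {
  if (is.null(Vbar)) Vbar <- fixed_point(net, h)
  A <- jacobian_at(net, Vbar)
  ev <- eigen(A)
  if (max(Re(ev$values)) >= 0)
    stop("linearized_covariance: Jacobian is unstable, no stationary covariance")
  tn <- noise$tau_noise
  N <- net$N
  # cross block: (A - I/tau_noise) P_vn = -T^{-1} Sigma
  rhs <- -sweep(noise$Sigma, 1, net$tau, "/")
  Pvn <- solve(A - diag(N) / tn, rhs)
  # voltage block: A Pvv + Pvv A' + Q = 0, Q = T^{-1} Pvn' + Pvn T^{-1}
  M <- sweep(t(Pvn), 1, net$tau, "/")
  Q <- M + t(M)
  S <- ev$vectors
  Sinv <- solve(S)
  Qt <- Sinv %*% Q %*% t(Sinv)
  denom <- outer(ev$values, ev$values, `+`)
  Pt <- -Qt / denom
  Pvv <- Re(S %*% Pt %*% t(S))
  Pvv <- (Pvv + t(Pvv)) / 2
  attr(Pvv, "Vbar") <- as.numeric(Vbar)
  Pvv
}
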