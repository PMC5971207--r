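# Circular-Gaussian bump over threshold-referenced voltage:
# g_i(mu, sigma) = exp((cos(theta_i - mu) - 1) / sigma^2), angles in radians.
bump_profile <- function(theta_rad, mu, sigma) {
  exp((cos(theta_rad - mu) - 1) / sigma^2)
}

# Amplitude solving the total-rate constraint sum_i k (a g_i)^n = R for the
# power law (g > 0 so the rectification is inactive for a > 0); closed form.
bump_amplitude <- function(g, nl, R) {
  (R / (nl$k * sum(g^nl$n)))^(1 / nl$n)
}

#' Fit bump kinetics to population voltage trajectories
#'
#' Fits a circular-Gaussian activity bump
#' `V_i(t) - V0 = a(t) exp[(cos(theta_i - mu(t)) - 1) / sigma(t)^2]`
#' to the excitatory population at every stored time step. Location `mu`
#' and width `sigma` are free; the amplitude `a` is set at each step so
#' that the total population firing rate implied by the bump equals a
#' constant target `R` (the time-mean total rate unless supplied) — for
#' the threshold power law that constraint has a closed-form solution.
#' `(mu, sigma)` minimize the squared voltage residual by Nelder-Mead,
#' initialized at the circular center of mass and spread and warm-started
#' from the previous step.
#'
#' Voltages are referenced to the rectification threshold `V0` of the
#' nonlinearity, the natural baseline of the power law.
#'
#' @param V `time x N` matrix or `time x N x trials` array of E-cell
#'   membrane potentials (mV).
#' @param theta E-cell angles (degrees on the full circle).
#' @param nl the network's [nonlinearity()] (kind `"powerlaw"`).
#' @param R_target total population rate target (1/s); default: time mean
#'   of the summed rates.
#' @return an object of class `bump_fit`: `series` (data.frame with
#'   `time_index`, `trial`, `a`, `mu_deg`, `sigma_deg`, `sse`, `flagged`),
#'   `var_captured` (fraction of threshold-referenced Vm variance pooled
#'   jointly over cells, time and trials captured by the fit),
#'   `var_captured_by_trial` (mean of per-trial fractions),
#'   `var_captured_fluct` (fraction of the temporal fluctuations only,
#'   per-cell means removed), `R_target`.
#' @export
bump_fit <- function(V, theta, nl, R_target = NULL) {
  if (length(dim(V)) == 2) V <- array(V, c(dim(V), 1))
  n_t <- dim(V)[1]; N <- dim(V)[2]; n_tr <- dim(V)[3]
  stopifnot(length(theta) == N, nl$kind == "powerlaw")
  th <- theta * pi / 180
  if (is.null(R_target)) {
    rt <- eval_nonlinearity(nl, V)
    R_target <- mean(apply(rt, c(1, 3), sum))
  }
  obj <- function(p, Vd) {
    sigma <- exp(p[2])
    g <- bump_profile(th, p[1], sigma)
    a <- bump_amplitude(g, nl, R_target)
    sum((Vd - a * g)^2)
  }
  rows <- vector("list", n_t * n_tr)
  fit_arr <- array(NA_real_, c(n_t, N, n_tr))
  ri <- 0L
  for (tr in seq_len(n_tr)) {
    p_prev <- NULL
    for (ti in seq_len(n_t)) {
      Vd <- V[ti, , tr] - nl$V0
      w <- pmax(Vd, 0)
      if (is.null(p_prev)) {
        z <- sum(w * exp(1i * th))
        mu0 <- Arg(z)
        Rbar <- min(max(Mod(z) / sum(w), 1e-3), 1 - 1e-6)
        sig0 <- max(sqrt(-2 * log(Rbar)), 0.1)
        p_prev <- c(mu0, log(sig0))
      }
      op <- stats::optim(p_prev, obj, Vd = Vd, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-10))
      flagged <- op$convergence != 0
      sigma <- exp(op$par[2])
      g <- bump_profile(th, op$par[1], sigma)
      a <- bump_amplitude(g, nl, R_target)
      fit_arr[ti, , tr] <- a * g
      p_prev <- op$par
      ri <- ri + 1L
      rows[[ri]] <- c(ti, tr, a, (op$par[1] * 180 / pi) %% 360,
                      sigma * 180 / pi, op$value, as.numeric(flagged))
    }
  }
  series <- as.data.frame(do.call(rbind, rows))
  names(series) <- c("time_index", "trial", "a", "mu_deg", "sigma_deg",
                     "sse", "flagged")
  Vd_all <- V - nl$V0
  res_all <- Vd_all - fit_arr
  # primary: variance pooled jointly over cells, time and trials (the
  # across-cell structure of the bump is part of the Vm variability)
  frac_of <- function(tr_idx) {
    v <- Vd_all[, , tr_idx, drop = FALSE]
    res <- res_all[, , tr_idx, drop = FALSE]
    1 - sum((res - mean(res))^2) / sum((v - mean(v))^2)
  }
  var_captured <- frac_of(seq_len(n_tr))
  var_by_trial <- mean(vapply(seq_len(n_tr), frac_of, 1))
  # secondary: fluctuations only (per-cell temporal means removed)
  tot_f <- sum(apply(Vd_all, 2, function(m) sum((m - mean(m))^2)))
  res_f <- sum(apply(res_all, 2, function(m) sum((m - mean(m))^2)))
  structure(list(series = series, var_captured = var_captured,
                 var_captured_by_trial = var_by_trial,
                 var_captured_fluct = 1 - res_f / tot_f,
                 R_target = R_target, theta = theta, nl = nl,
                 fitted = fit_arr),
            class = "bump_fit")
}

#' @export
print.bump_fit <- function(x, ...) {
  cat(sprintf("<bump_fit> %d frames, variance captured = %.1f%% (pooled), %.1f%% (per-trial mean)\n",
              nrow(x$series), 100 * x$var_captured, 100 * x$var_captured_by_trial))
  invisible(x)
}

#' Covariance templates of bump kinetics
#'
#' Differential activity patterns of the two principal bump modes —
#' sideways motion (`d V / d mu`) and width change (`d V / d sigma`,
#' including the amplitude change `d a / d sigma` induced by the
#' constant-total-rate constraint) — evaluated at the mean fitted bump,
#' scaled into covariance templates by the variances and covariance of
#' the fitted `(mu, sigma)` series:
#' `T = Var(mu) p_mu p_mu' + Var(sigma) p_sig p_sig'
#'    + Cov(mu, sigma) (p_mu p_sig' + p_sig p_mu')`.
#'
#' @param fit a [bump_fit()] object.
#' @param empirical_cov optional empirical Vm covariance (`N x N`) for an
#'   elementwise comparison report.
#' @return list with `T_mu`, `T_sigma`, `T_cross`, `T_total`, the
#'   patterns `p_mu`, `p_sigma`, mean bump parameters, and (if
#'   `empirical_cov` given) `report` with the correlation and relative
#'   Frobenius error between template-sum and empirical covariance.
#' @export
covariance_templates <- function(fit, empirical_cov = NULL) {
  th <- fit$theta * pi / 180
  s <- fit$series[fit$series$flagged == 0, ]
  mu_r <- s$mu_deg * pi / 180
  mu_bar <- Arg(sum(exp(1i * mu_r)))
  sig_r <- s$sigma_deg * pi / 180
  sig_bar <- mean(sig_r)
  dmu <- Arg(exp(1i * (mu_r - mu_bar)))   # wrapped deviations
  var_mu <- stats::var(dmu)
  var_sig <- stats::var(sig_r)
  cov_ms <- stats::cov(dmu, sig_r)
  nl <- fit$nl
  bump_V <- function(mu, sigma) {
    g <- bump_profile(th, mu, sigma)
    bump_amplitude(g, nl, fit$R_target) * g
  }
  g0 <- bump_profile(th, mu_bar, sig_bar)
  a0 <- bump_amplitude(g0, nl, fit$R_target)
  p_mu <- a0 * g0 * sin(th - mu_bar) / sig_bar^2
  eps <- 1e-5
  p_sig <- (bump_V(mu_bar, sig_bar + eps) - bump_V(mu_bar, sig_bar - eps)) / (2 * eps)
  T_mu <- var_mu * tcrossprod(p_mu)
  T_sigma <- var_sig * tcrossprod(p_sig)
  T_cross <- cov_ms * (tcrossprod(p_mu, p_sig) + tcrossprod(p_sig, p_mu))
  T_total <- T_mu + T_sigma + T_cross
  out <- list(T_mu = T_mu, T_sigma = T_sigma, T_cross = T_cross,
              T_total = T_total, p_mu = p_mu, p_sigma = p_sig,
              a = a0, mu_deg = (mu_bar * 180 / pi) %% 360,
              sigma_deg = sig_bar * 180 / pi,
              var_mu = var_mu, var_sigma = var_sig, cov_mu_sigma = cov_ms)
  if (!is.null(empirical_cov)) {
    lo <- lower.tri(T_total)
    out$report <- list(
      correlation = stats::cor(T_total[lo], empirical_cov[lo]),
      rel_frobenius = norm(T_total - empirical_cov, "F") / norm(empirical_cov, "F"))
  }
  out
}
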