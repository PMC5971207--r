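#' Fano factors and pairwise spike-count correlations
#'
#' Across-trial spike-count statistics for one condition: per-neuron Fano
#' factor (variance over mean of counts across trials) and the Pearson
#' correlation matrix. Neurons whose mean count does not exceed
#' `mean_min` are flagged (`usable = FALSE`) rather than divided:
#' near-zero rates make Fano and correlation estimates unstable.
#'
#' @param counts a `trials x neurons` matrix of spike counts.
#' @param mean_min minimum mean count for a neuron to enter population
#'   summaries.
#' @return an object of class `variability_stats`: `fano`, `corr`,
#'   `mean_count`, `usable`, and `fano_mean` (population mean over usable
#'   neurons).
#' @export
fano_and_correlations <- function(counts, mean_min = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 trials")
  m <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  usable <- m > mean_min
  fano <- ifelse(usable, v / m, NA_real_)
  sdv <- sqrt(v)
  corr <- matrix(NA_real_, ncol(counts), ncol(counts))
  ok <- sdv > 0
  if (sum(ok) >= 2)
    corr[ok, ok] <- stats::cor(counts[, ok, drop = FALSE])
  diag(corr) <- 1
  structure(list(fano = fano, corr = corr, mean_count = m, usable = usable,
                 fano_mean = mean(fano[usable])),
            class = "variability_stats")
}

#' @export
print.variability_stats <- function(x, ...) {
  cat(sprintf("<variability_stats> %d neurons (%d usable), population-mean Fano = %.3f\n",
              length(x$fano), sum(x$usable), x$fano_mean))
  invisible(x)
}

#' Trial-normalized spike counts
#'
#' Divides each neuron's counts by its across-trial mean, so that the
#' trial mean of each column is exactly 1 and its variance times the mean
#' count recovers the Fano factor exactly
#' (`Var(c/m) = Var(c)/m^2 = Fano/m`). The normalization removes the
#' rank-1 covariance pattern that merely reflects the tuning of mean
#' rates, so factor analysis of these counts isolates genuinely shared
#' variability. All-zero (or below-threshold) neurons are dropped with a
#' message.
#'
#' @param counts a `trials x neurons` matrix.
#' @param mean_min minimum mean count; neurons at or below it are dropped.
#' @return the normalized `trials x kept-neurons` matrix with attribute
#'   `kept` (indices of retained neurons).
#' @export
normalized_counts <- function(counts, mean_min = 0) {
  counts <- as.matrix(counts)
  m <- colMeans(counts)
  keep <- which(m > mean_min)
  if (length(keep) < ncol(counts))
    message(sprintf("normalized_counts: dropped %d neuron(s) with mean count <= %g",
                    ncol(counts) - length(keep), mean_min))
  out <- sweep(counts[, keep, drop = FALSE], 2, m[keep], "/")
  attr(out, "kept") <- keep
  out
}

#' Factor analysis of normalized spike counts
#'
#' Decomposes the covariance of trial-normalized counts into a rank-`k`
#' shared part and a private part. In `"eigen"` mode the shared part is
#' the top-`k` eigencomponent of the covariance (the best rank-`k`
#' approximation in Frobenius norm); private variance is the remaining
#' diagonal. In `"ml"` mode a standard factor-analysis likelihood
#' (shared = `Lambda Lambda'`, private diagonal `Psi`) is maximized by
#' EM, with a small ridge on the covariance for numerical safety.
#'
#' @param nc normalized counts (`trials x neurons`), from
#'   [normalized_counts()].
#' @param k number of factors (`k = 0` gives all-private).
#' @param mode `"eigen"` or `"ml"`.
#' @param ridge diagonal ridge added in `"ml"` mode.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return an object of class `factor_model`: `shared` (matrix),
#'   `private` (vector), `shared_var` (per-neuron diagonal of `shared`),
#'   `k`, `mode`, `converged`.
#' @export
factor_analysis <- function(nc, k = 3, mode = c("eigen", "ml"),
                            ridge = 1e-6, max_iter = 2000, tol = 1e-8) {
  mode <- match.arg(mode)
  C <- stats::cov(nc)
  p <- ncol(C)
  if (k == 0) {
    return(structure(list(shared = matrix(0, p, p), private = diag(C),
                          shared_var = rep(0, p), k = 0, mode = mode,
                          converged = TRUE), class = "factor_model"))
  }
  if (mode == "eigen") {
    eg <- eigen(C, symmetric = TRUE)
    kk <- seq_len(k)
    shared <- eg$vectors[, kk, drop = FALSE] %*%
      (eg$values[kk] * t(eg$vectors[, kk, drop = FALSE]))
    private <- diag(C) - diag(shared)
    conv <- TRUE
  } else {
    C <- C + ridge * diag(p)
    # EM for C ~ Lambda Lambda' + Psi on the sample covariance
    eg <- eigen(C, symmetric = TRUE)
    kk <- seq_len(k)
    Lambda <- eg$vectors[, kk, drop = FALSE] %*% diag(sqrt(pmax(eg$values[kk], 1e-12)), k)
    Psi <- pmax(diag(C) - rowSums(Lambda^2), 1e-8)
    ll_old <- -Inf; conv <- FALSE
    for (it in seq_len(max_iter)) {
      PsiInv <- 1 / Psi
      M <- diag(k) + t(Lambda) %*% (PsiInv * Lambda)
      Minv <- solve(M)
      beta <- Minv %*% t(PsiInv * Lambda)          # k x p
      CB <- C %*% t(beta)                           # p x k
      Ezz <- Minv + beta %*% CB                     # k x k
      Lambda_new <- CB %*% solve(Ezz)
      Psi_new <- pmax(diag(C) - rowSums(Lambda_new * CB), 1e-10)
      Lambda <- Lambda_new; Psi <- Psi_new
      S <- Lambda %*% t(Lambda) + diag(Psi)
      ll <- -0.5 * (determinant(S)$modulus + sum(diag(solve(S, C))))
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) { conv <- TRUE; break }
      ll_old <- ll
    }
    if (!conv) warning("factor_analysis: EM did not converge; returning best iterate")
    shared <- Lambda %*% t(Lambda)
    private <- Psi
  }
  structure(list(shared = shared, private = private,
                 shared_var = diag(shared), k = k, mode = mode,
                 converged = conv),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> k = %d (%s mode), mean shared variance = %.4f, mean private = %.4f\n",
              x$k, x$mode, mean(x$shared_var), mean(x$private)))
  invisible(x)
}

# Signed circular difference on a circle of the given period, in (-p/2, p/2].
circ_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Correlations averaged by tuning similarity
#'
#' Classifies neuron pairs into similarly tuned (preferred-orientation
#' difference below `split`) and orthogonally tuned (above `split`), and
#' averages their correlations as a function of the stimulus orientation
#' relative to the pair-average preferred orientation. Ring angles are on
#' the full 360-degree (direction) circle; orientation readouts halve
#' them, so preferred orientations live on a 180-degree circle and the
#' similar/orthogonal split defaults to 45 degrees of orientation.
#'
#' @param corr neuron-by-neuron correlation matrix.
#' @param theta per-neuron ring angle (degrees on the full circle).
#' @param theta_stim stimulus angle (degrees on the full circle).
#' @param split similar/orthogonal threshold on orientation difference
#'   (degrees).
#' @param n_bins number of bins for the stimulus-relative orientation axis.
#' @return a data.frame with columns `rel_orientation` (bin center,
#'   degrees), `class` (`"similar"`/`"orthogonal"`), `corr` (mean), `n`
#'   (pair count); attribute `depth` holds the peak-to-trough modulation
#'   per class.
#' @export
tuning_averaged_correlations <- function(corr, theta, theta_stim = 0,
                                         split = 45, n_bins = 12) {
  po <- (theta / 2) %% 180
  po_stim <- (theta_stim / 2) %% 180
  n <- length(theta)
  pairs <- which(upper.tri(corr), arr.ind = TRUE)
  cc <- corr[pairs]
  ok <- !is.na(cc)
  pairs <- pairs[ok, , drop = FALSE]; cc <- cc[ok]
  dpo <- abs(circ_diff(po[pairs[, 1]], po[pairs[, 2]], 180))
  mean_po <- po[pairs[, 2]] + circ_diff(po[pairs[, 1]], po[pairs[, 2]], 180) / 2
  rel <- circ_diff(po_stim, mean_po, 180)   # stimulus relative to pair PO
  cls <- ifelse(dpo < split, "similar", "orthogonal")
  edges <- seq(-90, 90, length.out = n_bins + 1)
  bin <- cut(rel, edges, include.lowest = TRUE)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- do.call(rbind, lapply(c("similar", "orthogonal"), function(cl) {
    sel <- cls == cl
    mm <- tapply(cc[sel], bin[sel], mean)
    nn <- tapply(cc[sel], bin[sel], length)
    data.frame(rel_orientation = centers, class = cl,
               corr = as.numeric(mm), n = as.integer(ifelse(is.na(nn), 0, nn)))
  }))
  depth <- vapply(c(similar = "similar", orthogonal = "orthogonal"), function(cl) {
    v <- out$corr[out$class == cl & out$n > 0]
    diff(range(v, na.rm = TRUE))
  }, 1)
  attr(out, "depth") <- depth
  out
}

#' Welch power spectral density
#'
#' Averaged periodogram with Hann windows, configurable overlap, and
#' per-segment linear detrending.
#'
#' @param x signal vector, or `time x trials` matrix (segments pooled
#'   across columns).
#' @param fs sampling frequency (Hz).
#' @param window_s window length (s).
#' @param overlap fractional overlap between windows.
#' @return a data.frame `freq` (Hz), `power` (one-sided PSD), with
#'   attribute `n_segments`.
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  w <- welch_cross(x, x, fs, window_s, overlap)
  out <- data.frame(freq = w$freq, power = Re(w$Pxy))
  attr(out, "n_segments") <- w$n_segments
  out
}

# Averaged cross-spectrum of x and y (same shape); returns complex Pxy.
welch_cross <- function(x, y, fs, window_s = 1, overlap = 0.5) {
  if (is.null(dim(x))) { x <- matrix(x); y <- matrix(y) }
  nw <- round(window_s * fs)
  step <- max(1, round(nw * (1 - overlap)))
  nt <- nrow(x)
  if (nt < 2 * nw) stop("segment shorter than two windows")
  starts <- seq(1, nt - nw + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))   # Hann
  U <- sum(win^2)
  nf <- nw %/% 2
  acc <- complex(nf)
  n_seg <- 0L
  tt <- seq_len(nw)
  for (col in seq_len(ncol(x))) for (s in starts) {
    xs <- x[s:(s + nw - 1), col]; ys <- y[s:(s + nw - 1), col]
    xs <- stats::resid(stats::lm.fit(cbind(1, tt), xs))
    ys <- stats::resid(stats::lm.fit(cbind(1, tt), ys))
    X <- stats::fft(xs * win); Y <- stats::fft(ys * win)
    acc <- acc + (X * Conj(Y))[2:(nf + 1)]
    n_seg <- n_seg + 1L
  }
  Pxy <- 2 * acc / (n_seg * U * fs)
  list(freq = (seq_len(nf)) * fs / nw, Pxy = Pxy, n_segments = n_seg)
}

#' Spectra and Vm-LFP coherence
#'
#' Welch power spectra of the LFP and magnitude-squared coherence between
#' single-cell Vm and the LFP, averaged across the supplied cells. LFP
#' power can be normalized to unit total power per condition so that
#' spectral shape changes are comparable across conditions.
#'
#' @param lfp LFP signal: vector or `time x trials` matrix.
#' @param vm `time x cells` matrix or `time x cells x trials` array of
#'   single-cell Vm aligned with `lfp`.
#' @param fs sampling frequency (Hz).
#' @param window_s,overlap Welch parameters.
#' @param normalize normalize LFP power to unit area.
#' @return list with `psd` (data.frame `freq`, `power`) and `coherence`
#'   (data.frame `freq`, `coherence`, `se` across cells).
#' @export
spectra_and_coherence <- function(lfp, vm, fs, window_s = 1, overlap = 0.5,
                                  normalize = TRUE) {
  psd <- welch_psd(lfp, fs, window_s, overlap)
  if (normalize) psd$power <- psd$power / sum(psd$power)
  if (length(dim(vm)) == 2) vm <- array(vm, c(dim(vm), 1))
  if (is.null(dim(lfp))) lfp <- matrix(lfp)
  n_cells <- dim(vm)[2]
  Pll <- Re(welch_cross(lfp, lfp, fs, window_s, overlap)$Pxy)
  coh <- sapply(seq_len(n_cells), function(ci) {
    v <- vm[, ci, , drop = TRUE]
    if (is.null(dim(v))) v <- matrix(v)
    Pvv <- welch_cross(v, v, fs, window_s, overlap)
    Pvl <- welch_cross(v, lfp, fs, window_s, overlap)
    Mod(Pvl$Pxy)^2 / (Re(Pvv$Pxy) * Pll)
  })
  coh <- matrix(coh, ncol = n_cells)
  list(psd = psd,
       coherence = data.frame(freq = psd$freq,
                              coherence = rowMeans(coh),
                              se = apply(coh, 1, stats::sd) / sqrt(n_cells)))
}

#' Timescales of variability suppression and recovery
#'
#' Given the across-trial variance trajectory around a step stimulus,
#' extracts the suppression half-time (first crossing of the midpoint
#' between baseline and plateau after stimulus onset, minus the onset
#' latency) and the recovery half-time (analogously after offset), plus
#' the suppression percentage `100 (baseline - plateau) / baseline`.
#' Latency is the last time the trajectory remains inside the baseline
#' noise band (mean +/- `band_se` standard errors) before heading to the
#' new level, so reported time constants discard latencies.
#'
#' @param var_t across-trial variance trajectory (vector).
#' @param times time axis (ms), same length.
#' @param t_on,t_off stimulus onset and offset (ms).
#' @param baseline_window,plateau_window time windows (ms, length-2) over
#'   which baseline and plateau variance are averaged. Defaults: from
#'   half of the pre-stimulus period to onset, and the second half of the
#'   stimulus period.
#' @param band_se width of the latency noise band in baseline standard
#'   errors.
#' @return an object of class `timescale_result`: `suppression_half_ms`,
#'   `recovery_half_ms`, `suppression_pct`, `baseline`, `plateau`,
#'   `latency_on_ms`, `latency_off_ms`.
#' @export
variability_timescales <- function(var_t, times, t_on, t_off,
                                   baseline_window = NULL,
                                   plateau_window = NULL,
                                   band_se = 2) {
  stopifnot(length(var_t) == length(times))
  if (is.null(baseline_window)) baseline_window <- c(t_on / 2, t_on)
  if (is.null(plateau_window)) plateau_window <- c((t_on + t_off) / 2, t_off)
  in_win <- function(w) times > w[1] & times <= w[2]
  base_v <- var_t[in_win(baseline_window)]
  baseline <- mean(base_v)
  base_se <- stats::sd(base_v) / sqrt(length(base_v))
  plateau <- mean(var_t[in_win(plateau_window)])
  if (abs(baseline - plateau) < .Machine$double.eps^0.5 * (baseline + plateau) ||
      !is.finite(baseline) || !is.finite(plateau) || baseline == plateau)
    stop("undefined timescale: baseline equals plateau")
  half <- (baseline + plateau) / 2
  band <- band_se * base_se
  suppressing <- baseline > plateau

  half_time <- function(t_from, lev_from, lev_to) {
    idx <- which(times > t_from)
    v <- var_t[idx]; tt <- times[idx]
    goal_dir <- sign(lev_to - lev_from)
    crossed <- if (goal_dir < 0) v <= half else v >= half
    if (!any(crossed)) stop("undefined timescale: no half crossing found")
    t_half <- tt[which(crossed)[1]]
    # latency: last time still inside the band around the starting level
    inside <- abs(v - lev_from) <= band
    pre <- which(inside & tt < t_half)
    t_lat <- if (length(pre)) tt[max(pre)] else t_from
    c(half = t_half - t_lat, latency = t_lat - t_from)
  }
  sup <- half_time(t_on, baseline, plateau)
  rec <- half_time(t_off, plateau, baseline)
  structure(list(suppression_half_ms = unname(sup["half"]),
                 recovery_half_ms = unname(rec["half"]),
                 suppression_pct = 100 * (baseline - plateau) / baseline,
                 baseline = baseline, plateau = plateau,
                 latency_on_ms = unname(sup["latency"]),
                 latency_off_ms = unname(rec["latency"]),
                 suppressing = suppressing),
            class = "timescale_result")
}

#' @export
print.timescale_result <- function(x, ...) {
  cat(sprintf("<timescale_result> suppression %.1f%%; half-times: suppression %.1f ms, recovery %.1f ms\n",
              x$suppression_pct, x$suppression_half_ms, x$recovery_half_ms))
  invisible(x)
}

#' Orientation tuning curve fit and tuning index
#'
#' Fits `f(theta) = f0 + fm * exp(kappa (cos(2 (theta - theta_pref)) - 1))`
#' to rate-versus-orientation data by nonlinear least squares and derives
#' the orientation tuning index
#' `OTI = (f(theta_pref) - f(theta_orth)) / (f(theta_pref) + f(theta_orth))`
#' with `theta_orth = theta_pref + 90` degrees. The standard selection
#' predicate (`OTI >= 0.75` and evoked rate `>= 1` spike/s) is exposed.
#'
#' @param theta stimulus orientations (degrees, on the 180-degree circle).
#' @param rate mean evoked rates (1/s), same length; at least 4 conditions.
#' @param oti_min,rate_min selection thresholds.
#' @return an object of class `tuning_fit`: `f0`, `fm`, `kappa`,
#'   `theta_pref` (degrees), `oti`, `mean_rate`, `selected`, `converged`.
#' @export
tuning_and_oti <- function(theta, rate, oti_min = 0.75, rate_min = 1) {
  stopifnot(length(theta) == length(rate))
  if (length(unique(theta %% 180)) < 4) stop("need at least 4 orientation conditions")
  th <- theta * pi / 180
  p0 <- c(f0 = max(min(rate), 1e-3), fm = max(max(rate) - min(rate), 1e-3),
          kappa = 1, thp = th[which.max(rate)])
  fitfun <- function(p) p["f0"] + p["fm"] * exp(p["kappa"] * (cos(2 * (th - p["thp"])) - 1))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) rate - fitfun(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(f0 = NA, fm = NA, kappa = NA, theta_pref = NA,
                          oti = NA, mean_rate = mean(rate), selected = FALSE,
                          converged = FALSE), class = "tuning_fit"))
  }
  p <- fit$par
  if (p[["fm"]] < 0) {  # reparameterize: negative amplitude = pref shifted 90 deg
    p[["fm"]] <- -p[["fm"]]; p[["thp"]] <- p[["thp"]] + pi / 2
  }
  f_pref <- p[["f0"]] + p[["fm"]]
  f_orth <- p[["f0"]] + p[["fm"]] * exp(-2 * p[["kappa"]])
  oti <- (f_pref - f_orth) / (f_pref + f_orth)
  mean_rate <- mean(rate)
  structure(list(f0 = p[["f0"]], fm = p[["fm"]], kappa = p[["kappa"]],
                 theta_pref = (p[["thp"]] * 180 / pi) %% 180,
                 oti = oti, mean_rate = mean_rate,
                 selected = is.finite(oti) && oti >= oti_min && mean_rate >= rate_min,
                 converged = TRUE),
            class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("<tuning_fit> pref = %.1f deg, OTI = %.3f, mean rate = %.2f Hz, selected = %s\n",
              x$theta_pref, x$oti, x$mean_rate, x$selected))
  invisible(x)
}

#' Gaussian temporal smoothing
#'
#' Smooths a signal with a truncated Gaussian kernel (+/- 3 sd),
#' normalized at the edges. Population rates, LFP and Vm traces are
#' conventionally displayed and compared after such smoothing, which
#' isolates the slow (shared) component of variability from fast
#' spiking-driven fluctuations.
#'
#' @param x signal vector or `time x k` matrix (columns smoothed
#'   independently).
#' @param sd_ms kernel standard deviation (ms).
#' @param dt_ms sampling interval of `x` (ms).
#' @return smoothed signal, same shape.
#' @export
smooth_gaussian <- function(x, sd_ms, dt_ms) {
  half <- max(1L, ceiling(3 * sd_ms / dt_ms))
  kk <- stats::dnorm(seq(-half, half) * dt_ms, sd = sd_ms)
  kk <- kk / sum(kk)
  sm_one <- function(v) {
    n <- length(v)
    out <- stats::filter(v, kk, sides = 2)
    # renormalize near the edges where the kernel is truncated
    wts <- stats::filter(rep(1, n), kk, sides = 2)
    v2 <- as.numeric(out / wts)
    idx <- which(is.na(v2))
    for (i in idx) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      w <- kk[(lo - i + half + 1):(hi - i + half + 1)]
      v2[i] <- sum(v[lo:hi] * w) / sum(w)
    }
    v2
  }
  if (is.matrix(x)) apply(x, 2, sm_one) else sm_one(x)
}
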