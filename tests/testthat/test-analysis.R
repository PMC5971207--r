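test_that("Fano and correlation basics: degenerate and Poisson inputs", {
  expect_error(fano_and_correlations(matrix(1, 1, 3)), "2 trials")
  # identical rows: zero variance, flagged correlations
  st <- fano_and_correlations(matrix(2, 10, 4))
  expect_equal(unname(st$fano), rep(0, 4))
  expect_true(all(is.na(st$corr[upper.tri(st$corr)])))
  # frozen rate -> Poisson counts -> Fano near 1
  set.seed(1)
  cc <- matrix(rpois(400 * 30, 3), 400, 30)
  st2 <- fano_and_correlations(cc)
  expect_equal(st2$fano_mean, 1, tolerance = 0.05)
  expect_true(isSymmetric(st2$corr))
  expect_equal(diag(st2$corr), rep(1, 30))
  # zero-mean neuron flagged, not divided
  cc[, 1] <- 0
  st3 <- fano_and_correlations(cc)
  expect_false(st3$usable[1])
  expect_true(is.na(st3$fano[1]))
})

test_that("normalized counts have unit means and variances equal to Fano exactly", {
  set.seed(2)
  cc <- matrix(rpois(200 * 20, lambda = rep(c(2, 5), each = 10) *
                       rep(exp(rnorm(200, 0, 0.3)), times = 20)), 200, 20)
  nc <- normalized_counts(cc)
  expect_equal(unname(colMeans(nc)), rep(1, 20))
  st <- fano_and_correlations(cc)
  # exact identity: Var(c/mean) * mean = Var(c)/mean = Fano
  expect_equal(unname(apply(nc, 2, var) * colMeans(cc)), unname(st$fano),
               tolerance = 1e-12)
  # constant counts -> all ones
  expect_true(all(normalized_counts(matrix(3, 5, 2)) == 1))
  # all-zero neuron dropped with a message
  cc[, 3] <- 0
  expect_message(nc2 <- normalized_counts(cc), "dropped 1")
  expect_equal(ncol(nc2), 19)
})

test_that("eigen-mode factor analysis is the exact best rank-k split", {
  set.seed(3)
  nc <- matrix(rnorm(500 * 12), 500, 12) %*% diag(sqrt(seq(0.5, 3, length.out = 12)))
  C <- cov(nc)
  fm <- factor_analysis(nc, k = 3, mode = "eigen")
  # diagonal additivity: shared + private variance = total exactly
  expect_equal(fm$shared_var + fm$private, diag(C), tolerance = 1e-12)
  # best rank-3 Frobenius approximation: error equals tail eigenvalues
  eg <- eigen(C, symmetric = TRUE)
  expect_equal(norm(C - fm$shared, "F"), sqrt(sum(eg$values[4:12]^2)),
               tolerance = 1e-10)
  expect_equal(qr(fm$shared)$rank, 3)
  # k = 0: all variance private
  fm0 <- factor_analysis(nc, k = 0)
  expect_equal(fm0$private, diag(C))
  expect_equal(fm0$shared, matrix(0, 12, 12))
})

test_that("factor analysis recovers injected rank-1 shared variability", {
  set.seed(4)
  n_tr <- 2000; p <- 30
  load <- runif(p, 0.5, 1.5)
  z <- rnorm(n_tr)
  x <- outer(z, load) + matrix(rnorm(n_tr * p, sd = 0.7), n_tr, p)
  truth <- mean(load^2)
  for (mode in c("eigen", "ml")) {
    fm <- factor_analysis(x, k = 1, mode = mode)
    expect_equal(mean(fm$shared_var), truth, tolerance = 0.05)
  }
})

test_that("tuning-averaged correlations classify and bin pairs correctly", {
  th <- seq(0, 360, length.out = 21)[1:20]
  # uniform correlation matrix -> both curves flat at that value
  corr <- matrix(0.3, 20, 20); diag(corr) <- 1
  tc <- tuning_averaged_correlations(corr, th, theta_stim = 0, n_bins = 6)
  expect_true(all(abs(tc$corr[tc$n > 0] - 0.3) < 1e-12))
  expect_equal(unname(attr(tc, "depth")), c(0, 0), tolerance = 1e-12)
  # pair on the same ring angle is "similar", opposite ring angle is "orthogonal"
  expect_equal(unique(tc$class), c("similar", "orthogonal"))
})

test_that("Welch spectra and coherence behave on known signals", {
  fs <- 1000
  t <- seq(0, 8, by = 1 / fs)[-1]
  x <- sin(2 * pi * 40 * t) + 0.1 * rnorm(length(t))
  psd <- welch_psd(x, fs, window_s = 1)
  expect_equal(psd$freq[which.max(psd$power)], 40, tolerance = 1e-9)
  # identical signals -> coherence 1 everywhere
  sc <- spectra_and_coherence(x, matrix(x), fs, window_s = 1)
  expect_true(all(sc$coherence$coherence > 0.999))
  # independent white noise -> low coherence
  set.seed(5)
  y <- rnorm(length(t))
  sc2 <- spectra_and_coherence(x, matrix(y), fs, window_s = 0.5)
  expect_lt(mean(sc2$coherence$coherence), 0.2)
  expect_error(welch_psd(x[1:500], fs, window_s = 1), "two windows")
})

test_that("timescale extraction recovers tau*log(2) for an exponential relaxation", {
  tt <- seq(1, 3000, by = 1)
  tau <- 60; base <- 2; plat <- 0.5
  v <- ifelse(tt <= 1000, base,
       ifelse(tt <= 2000, plat + (base - plat) * exp(-(tt - 1000) / tau),
              base + (plat - base) * exp(-(tt - 2000) / tau)))
  ts <- variability_timescales(v, tt, t_on = 1000, t_off = 2000)
  expect_equal(ts$suppression_half_ms, tau * log(2), tolerance = 0.05)
  expect_equal(ts$recovery_half_ms, tau * log(2), tolerance = 0.05)
  expect_equal(ts$suppression_pct, 100 * (base - plat) / base, tolerance = 0.02)
  # flat trajectory: undefined timescales
  expect_error(variability_timescales(rep(1, 3000), tt, 1000, 2000),
               "baseline equals plateau")
})

test_that("orientation tuning fit recovers parameters and the OTI closed forms", {
  th <- seq(0, 157.5, by = 22.5)
  f <- function(th, f0, fm, kap, thp)
    f0 + fm * exp(kap * (cos(2 * (th - thp) * pi / 180) - 1))
  r <- f(th, f0 = 1, fm = 20, kap = 1.5, thp = 40)
  fit <- tuning_and_oti(th, r)
  expect_equal(fit$theta_pref, 40, tolerance = 0.01)
  expect_equal(fit$fm, 20, tolerance = 0.01)
  # fm = 0 -> OTI = 0
  fit0 <- tuning_and_oti(th, rep(5, 8) + c(1, -1) * 1e-9)
  expect_equal(fit0$oti, 0, tolerance = 1e-3)
  # f0 = 0 -> OTI = (1 - exp(-2 kappa)) / (1 + exp(-2 kappa))
  r2 <- f(th, f0 = 0, fm = 10, kap = 2, thp = 90)
  fit2 <- tuning_and_oti(th, r2)
  kap <- fit2$kappa
  expect_equal(fit2$oti, (1 - exp(-2 * kap)) / (1 + exp(-2 * kap)), tolerance = 1e-6)
  # selection predicate
  expect_true(fit2$selected)     # OTI ~ 0.96, mean rate > 1
  weak <- f(th, f0 = 5, fm = 1, kap = 0.5, thp = 10)
  expect_false(tuning_and_oti(th, weak)$selected)
  expect_error(tuning_and_oti(c(0, 45, 90), c(1, 2, 1)), "4 orientation")
})

test_that("Gaussian smoothing preserves means and suppresses fast components", {
  set.seed(6)
  slow <- sin(2 * pi * (1:2000) / 1000)
  fast <- rnorm(2000)
  x <- slow + fast
  sm <- smooth_gaussian(x, sd_ms = 20, dt_ms = 1)
  expect_lt(abs(mean(sm) - mean(x)), 0.01)
  expect_lt(var(sm - slow), 0.05 * var(fast))
})
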