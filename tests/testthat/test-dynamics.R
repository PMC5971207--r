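test_that("uncoupled noiseless unit shows the RC step response", {
  nl <- nonlinearity("powerlaw", k = 0.3, n = 2, V0 = -70)
  net <- network_spec(1, 0, matrix(0, 1, 1), tau = 20, Vrest = -70, nl = nl)
  sim <- integrate_network(net, stimulus_protocol(200, list(10)), noise = NULL,
                           dt = 0.1, seed = 1, record = "V", record_dt = 1)
  V <- sim$V[, 1, 1]
  expect_equal(V[200], -60, tolerance = 1e-3)            # converged to Vrest + h
  expect_equal(V[20], -70 + 10 * (1 - exp(-1)), tolerance = 0.05)  # 1 tau
})

test_that("without recurrence the stationary Vm std equals sigma_0 (amplitude scaling)", {
  tau_E <- 20; tau_n <- 50; s0 <- 0.3
  nl <- nonlinearity("powerlaw", k = 0.3, n = 2, V0 = -70)
  net <- network_spec(1, 0, matrix(0, 1, 1), tau = tau_E, Vrest = -70, nl = nl)
  ns <- noise_spec(tau_n, matrix(s0^2 * (1 + tau_E / tau_n), 1, 1))
  sim <- integrate_network(net, stimulus_protocol(3000, list(0)), ns, dt = 0.5,
                           seed = 4, n_trials = 200, record = "trial_stats",
                           record_dt = 2)
  v <- mean(sim$trial_var[sim$times > 1000, ])
  expect_equal(sqrt(v), s0, tolerance = 0.05)
  # and the linearized covariance gives sigma_0^2 exactly
  lc <- linearized_covariance(net, ns, 0)
  expect_equal(lc[1, 1], s0^2, tolerance = 1e-10)
})

test_that("integration is bit-reproducible given (seed, dt, n_trials)", {
  tp <- two_pop_model()
  prot <- stimulus_protocol(c(100, 100), list(2, 15))
  s1 <- integrate_network(tp$net, prot, tp$noise, dt = 0.1, seed = 7, n_trials = 3)
  s2 <- integrate_network(tp$net, prot, tp$noise, dt = 0.1, seed = 7, n_trials = 3)
  expect_identical(s1$V, s2$V)
  s3 <- integrate_network(tp$net, prot, tp$noise, dt = 0.1, seed = 8, n_trials = 3)
  expect_false(identical(s3$V, s1$V))
})

test_that("divergence triggers an instability error naming the first step", {
  nl <- nonlinearity("powerlaw", k = 0.3, n = 2, V0 = -70)
  net <- network_spec(1, 0, matrix(5, 1, 1), tau = 20, Vrest = -70, nl = nl)
  expect_error(
    integrate_network(net, stimulus_protocol(500, list(20)), NULL, dt = 0.1),
    "instability.*step")
})

test_that("dt above a tenth of the fastest time constant is refused", {
  tp <- two_pop_model()
  expect_error(
    integrate_network(tp$net, stimulus_protocol(10, list(0)), tp$noise, dt = 2),
    "dt must satisfy")
})

test_that("fixed point with W = 0 is exactly Vrest + h", {
  nl <- nonlinearity("powerlaw", k = 0.3, n = 2, V0 = -70)
  net <- network_spec(2, 0, matrix(0, 2, 2), tau = 20, Vrest = -70, nl = nl)
  fp <- fixed_point(net, c(3, 7))
  expect_equal(as.numeric(fp), c(-67, -63), tolerance = 1e-9)
})

test_that("relaxation and Newton agree on the two-population network", {
  tp <- two_pop_model()
  for (h in c(0, 2, 15)) {
    a <- fixed_point(tp$net, h, method = "relaxation")
    b <- fixed_point(tp$net, h, method = "newton")
    expect_lt(max(abs(a - b)), 1e-6)
    expect_true(attr(a, "stable"))
    expect_lt(attr(a, "residual"), 1e-8)
  }
})

test_that("effective weights vanish at threshold and grow with input", {
  tp <- two_pop_model()
  expect_equal(effective_weights(tp$net, c(-70, -70)), matrix(0, 2, 2))
  # entries scale linearly with the suprathreshold voltage for n = 2
  W1 <- effective_weights(tp$net, c(-69, -69))
  W2 <- effective_weights(tp$net, c(-68, -68))
  expect_equal(W2, 2 * W1, tolerance = 1e-12)
  # stimulus strengthens every effective connection
  We2 <- effective_weights(tp$net, fixed_point(tp$net, 2))
  We15 <- effective_weights(tp$net, fixed_point(tp$net, 15))
  expect_true(all(abs(We15) > abs(We2)))
})

test_that("linearized covariance solves the augmented Lyapunov system", {
  # uncoupled case: closed form sigma_0^2 on the diagonal, zero off-diagonal
  nl <- nonlinearity("powerlaw", k = 0.3, n = 2, V0 = -70)
  net <- network_spec(1, 1, matrix(0, 2, 2), tau = c(20, 10), Vrest = -70, nl = nl)
  s0 <- c(0.2, 0.1)
  ns <- noise_spec(50, diag(s0^2 * (1 + c(20, 10) / 50)))
  lc <- linearized_covariance(net, ns, 5)
  expect_equal(lc, diag(s0^2), tolerance = 1e-12, ignore_attr = TRUE)
  # residual of the voltage-block Lyapunov equation is numerically zero
  tp <- two_pop_model()
  fp <- fixed_point(tp$net, 2)
  P <- linearized_covariance(tp$net, tp$noise, 2, Vbar = fp)
  A <- sweep(effective_weights(tp$net, fp) - diag(2), 1, tp$net$tau, "/")
  tn <- tp$noise$tau_noise
  Pvn <- solve(A - diag(2) / tn, -sweep(tp$noise$Sigma, 1, tp$net$tau, "/"))
  M <- sweep(t(Pvn), 1, tp$net$tau, "/")
  expect_lt(max(abs(A %*% P + P %*% t(A) + M + t(M))), 1e-12)
})

test_that("linearized covariance matches simulation in the small-fluctuation regime", {
  # weak noise keeps the dynamics near-linear around the fixed point
  tp <- build_two_pop(sigma_0E = 0.02, sigma_0I = 0.01)
  lc <- linearized_covariance(tp$net, tp$noise, 15)
  sim <- integrate_network(tp$net, stimulus_protocol(2500, list(15)), tp$noise,
                           dt = 0.1, seed = 11, n_trials = 200,
                           record = "trial_stats", record_dt = 2)
  keep <- sim$times > 500
  mc <- colMeans(sim$trial_var[keep, ])
  expect_equal(mc[1], lc[1, 1], tolerance = 0.05)
  expect_equal(mc[2], lc[2, 2], tolerance = 0.05)
})

test_that("an unstable operating point is refused for covariance analysis", {
  nl <- nonlinearity("powerlaw", k = 0.3, n = 2, V0 = -70)
  net <- network_spec(1, 0, matrix(3, 1, 1), tau = 20, Vrest = -70, nl = nl)
  ns <- noise_spec(50, matrix(0.04, 1, 1))
  # V = -68 is far above the self-consistency region: force Vbar directly
  expect_error(linearized_covariance(net, ns, 0, Vbar = -65), "unstable")
})

test_that("fixed-point rates grow supralinearly then sublinearly, with I/E ratio rising", {
  tp <- two_pop_model()
  hs <- c(0.5, 1, 2, 4, 8, 12, 16, 20)
  rates <- t(vapply(hs, function(h)
    eval_nonlinearity(tp$net$nl, as.numeric(fixed_point(tp$net, h))), numeric(2)))
  # supralinear at small h: rate ratio grows faster than input ratio
  expect_gt(rates[2, 1] / rates[1, 1], 2)
  # sublinear at large h
  expect_lt(rates[8, 1] / rates[7, 1], 20 / 16)
  # inhibition gains on excitation monotonically
  expect_true(all(diff(rates[, 2] / rates[, 1]) > 0))
})
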