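test_that("realized connectivity has exact in-degrees and the J scaling contract", {
  spec <- cached("spiking_small", build_spiking_ssn(N_E = 400, N_I = 100, seed = 2))
  J <- spec$J
  expect_equal(as.numeric(Matrix::rowSums(J > 0)), rep(40, 500))   # p_E * N_E
  expect_equal(as.numeric(Matrix::rowSums(J < 0)), rep(40, 500))   # p_I * N_I
  # mean recurrent input equals the reduced model's W r for matched rates
  rE <- 5; rI <- 8; tau_syn_s <- 0.002
  a <- c(rep(rE * tau_syn_s, 400), rep(rI * tau_syn_s, 100))
  inp <- as.numeric(J %*% a)
  expect_equal(mean(inp[1:400]), 1.25 * rE - 0.65 * rI, tolerance = 1e-10)
  expect_equal(mean(inp[401:500]), 1.20 * rE - 0.50 * rI, tolerance = 1e-10)
})

test_that("with no synapses and frozen Vm the counts are Poisson (Fano near 1)", {
  spec <- build_spiking_ssn(N_E = 150, N_I = 50, seed = 3)
  spec$J <- spec$J * 0
  prot <- stimulus_protocol(3000, list(8))   # Vm settles at -62 -> 19.2 1/s
  sim <- simulate_spiking(spec, prot, noise = NULL, dt = 0.1, seed = 4,
                          n_trials = 8, record_dt = NA)
  counts <- bin_spikes(sim, bin_ms = 100, t_start = 200)
  # pool bins and trials as independent repeats; rate is constant
  pooled <- apply(counts, 2, as.numeric)
  fano <- apply(pooled, 2, var) / colMeans(pooled)
  expect_equal(mean(fano), 1, tolerance = 0.05)
  expect_equal(mean(colMeans(pooled)), 19.2 * 0.1, tolerance = 0.1)
})

test_that("no spike influences another neuron before the axonal delay", {
  # two neurons: 1 -> 2 with a huge synapse; neuron 1 driven hard
  spec <- build_spiking_ssn(N_E = 2, N_I = 0, p_E = 0.5, p_I = 0,
                            tau_E = 20, seed = 1)
  spec$J <- Matrix::sparseMatrix(i = 2, j = 1, x = 50, dims = c(2, 2))
  spec$K_E <- 1; spec$K_I <- 0
  prot <- stimulus_protocol(60, list(c(40, 0)))   # only neuron 1 driven
  sim <- simulate_spiking(spec, prot, noise = NULL, dt = 0.1, seed = 2,
                          n_trials = 1, record_dt = 0.1)
  sp <- sim$spikes[[1]]
  first <- min(sp$time_ms[sp$neuron == 1])
  V2 <- sim$V[, 2, 1]
  moved <- sim$times[which(abs(V2 - V2[1]) > 1e-9)[1]]
  expect_gte(moved, first + spec$delay - 1e-9)
})

test_that("the spiking network tracks the reduced rate model across an input step", {
  spec <- cached("spiking_mid", build_spiking_ssn(N_E = 1000, N_I = 250, seed = 2))
  noise <- uniform_noise_cov(1250, sigma_noise = 0.2 * sqrt(1 + 20 / 50), rho = 0.2)
  prot <- stimulus_protocol(c(600, 600), list(2, 15))
  sim <- simulate_spiking(spec, prot, noise, dt = 0.1, seed = 3, n_trials = 1,
                          record_dt = 2)
  sp <- sim$spikes[[1]]
  tp <- two_pop_model()
  for (seg in 1:2) {
    t0 <- c(250, 850)[seg]; t1 <- c(600, 1200)[seg]
    sel <- sp$time_ms > t0 & sp$time_ms <= t1
    rE <- sum(sel & sp$neuron <= 1000) / (1000 * (t1 - t0) / 1000)
    rI <- sum(sel & sp$neuron > 1000) / (250 * (t1 - t0) / 1000)
    fp <- fixed_point(tp$net, c(2, 15)[seg])
    rfp <- eval_nonlinearity(tp$net$nl, fp)
    expect_equal(rE, rfp[1], tolerance = 0.45)
    expect_equal(rI, rfp[2], tolerance = 0.45)
    # mean Vm tracks the reduced fixed point within a millivolt or so
    V <- sim$V[sim$times > t0 & sim$times <= t1, 1:1000, 1]
    expect_equal(mean(V), fp[1], tolerance = 0.02)
  }
  # smoothed (slow) LFP variability is quenched by the stronger input
  lfp <- lfp_proxy(sim$V[, , 1])
  sm <- smooth_gaussian(lfp, sd_ms = 25, dt_ms = 2)
  v_spont <- var(sm[sim$times > 250 & sim$times <= 600])
  v_evoked <- var(sm[sim$times > 850 & sim$times <= 1200])
  expect_lt(v_evoked, v_spont)
  assign("spiking_step_sim", sim, envir = .cache)
})

test_that("input-driven suppression acts on shared, not private, Vm variability", {
  sim <- get("spiking_step_sim", envir = .cache)
  V <- sim$V[, 1:1000, 1]
  sm <- smooth_gaussian(V[, seq(1, 1000, by = 20)], sd_ms = 25, dt_ms = 2)
  lfp <- rowMeans(smooth_gaussian(V[, seq(2, 1000, by = 4)], sd_ms = 25, dt_ms = 2))
  spont <- sim$times > 250 & sim$times <= 600
  evoked <- sim$times > 850 & sim$times <= 1200
  # shared (population-averaged, slow) variance is quenched ...
  expect_lt(var(lfp[evoked]), 0.8 * var(lfp[spont]))
  # ... while the private residual is not quenched at all (at this network
  # scale it even grows, via rate-dependent synaptic shot noise)
  priv <- function(win) mean(apply(sm[win, ] - lfp[win], 2, var))
  expect_gte(priv(evoked), 0.8 * priv(spont))
})

test_that("doubly stochastic Poisson counts obey the law of total variance", {
  # constant rate 10 1/s in 100 ms bins: mean 1, Fano 1
  lam <- array(1, c(40, 5, 200))
  cc <- poisson_counts(lam, seed = 6)
  expect_equal(mean(cc), 1, tolerance = 0.03)
  f <- apply(cc, 2, function(m) var(as.numeric(m)) / mean(m))
  expect_equal(mean(f), 1, tolerance = 0.05)
  # rates varying across trials: Fano = 1 + Var(lambda)/Mean(lambda)
  set.seed(8)
  lam_tr <- rep(exp(rnorm(400, 0, 0.5)), each = 1)     # per-trial rates
  lam2 <- array(rep(lam_tr, each = 1), c(1, 1, 400))
  cc2 <- as.numeric(poisson_counts(lam2, seed = 9))
  expected <- 1 + var(lam_tr) / mean(lam_tr)
  expect_equal(var(cc2) / mean(cc2), expected, tolerance = 0.2)
  expect_error(poisson_counts(array(-1, c(1, 1, 1))), "negative")
})

test_that("LFP proxy is the population average of Vm", {
  V <- matrix(rnorm(50), 10, 5)
  expect_equal(lfp_proxy(V), rowMeans(V))
  expect_equal(lfp_proxy(V, neurons = 2:3), rowMeans(V[, 2:3]))
  Vc <- matrix(-64.2, 10, 5)
  expect_equal(lfp_proxy(Vc), rep(-64.2, 10))
  expect_equal(var(lfp_proxy(Vc)), 0)
})
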