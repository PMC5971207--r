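#' Build a named architecture from a parameter list
#'
#' Dispatches on `type` to the concrete model builders, with defaults
#' equal to the standard parameter tables. Used by [run_experiment()] and
#' the command-line driver.
#'
#' @param type one of `"two_pop"`, `"ring_ssn"`, `"spiking_ssn"`,
#'   `"multi_attractor"`, `"chaotic"`.
#' @param params named list of overrides passed to the builder.
#' @return list with `net` (or `spec` for the spiking model), `noise`,
#'   optional `geometry`, and `input(segment)` mapping a protocol-segment
#'   description (fields `h` or `c`, `theta_stim`) to an input vector.
#' @export
build_architecture <- function(type, params = list()) {
  type <- match.arg(type, c("two_pop", "ring_ssn", "spiking_ssn",
                            "multi_attractor", "chaotic"))
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  if (type == "two_pop") {
    m <- do.call(build_two_pop, params)
    m$input <- function(seg) rep(seg$h, 2)
    m
  } else if (type == "ring_ssn") {
    geom <- ring_geometry(p("N_E", 50), p("N_I", 50),
                          ell_syn = p("ell_syn", 45),
                          ell_noise = p("ell_noise", 60),
                          ell_stim = p("ell_stim", 60))
    net_args <- params[intersect(names(params),
      c("W_EE", "W_IE", "W_EI", "W_II", "tau_E", "tau_I", "k", "n", "V0", "Vrest"))]
    net <- do.call(build_ring_ssn, c(list(geometry = geom), net_args))
    noise <- ring_noise_cov(geom, sigma_0E = p("sigma_0E", 1),
                            sigma_0I = p("sigma_0I", 0.5),
                            tau_E = p("tau_E", 20), tau_I = p("tau_I", 10),
                            tau_noise = p("tau_noise", 50))
    b <- p("b", 2); A_max <- p("A_max", 20)
    list(net = net, noise = noise, geometry = geom,
         input = function(seg) {
           if (!is.null(seg$h)) rep_len(seg$h, net$N)
           else ring_input(geom, c = seg$c, b = b, A_max = A_max,
                           theta_stim = if (is.null(seg$theta_stim)) 0 else seg$theta_stim)
         })
  } else if (type == "spiking_ssn") {
    spec <- do.call(build_spiking_ssn, params[setdiff(names(params),
      c("sigma_noise", "rho", "tau_noise"))])
    noise <- uniform_noise_cov(spec$N, sigma_noise = p("sigma_noise", 0.2 * sqrt(1 + 20 / 50)),
                               rho = p("rho", 0.2), tau_noise = p("tau_noise", 50))
    list(spec = spec, noise = noise,
         input = function(seg) rep(seg$h, spec$N))
  } else if (type == "multi_attractor") {
    m <- do.call(build_multiattractor, params)
    inp <- m$input
    m$input <- function(seg) {
      if (!is.null(seg$h)) rep_len(seg$h, m$net$N)
      else inp(c = seg$c, theta_stim = if (is.null(seg$theta_stim)) 0 else seg$theta_stim)
    }
    m
  } else {
    m <- do.call(build_chaotic, params)
    inp <- m$input
    m$input <- function(seg) {
      if (!is.null(seg$h)) rep_len(seg$h, m$net$N) else inp(c = seg$c)
    }
    m
  }
}

#' Run a configured experiment
#'
#' Executes a fully serializable experiment configuration: builds the
#' architecture, assembles the stimulus protocol, integrates the
#' requested number of trials, and applies the requested analyses.
#' Re-running the same configuration reproduces every stochastic output
#' exactly (all randomness derives from `config$seed`).
#'
#' @param config a named list (or path to a YAML file) with elements
#'   `architecture` (list: `type`, `params`), `protocol` (list of
#'   segments, each with `duration_ms` and `h` or `c` and optional
#'   `theta_stim`), `n_trials`, `dt`, `seed`, optional `record`,
#'   `record_dt`, `rate_bin_ms`, `V_init`, `init_sd`, `analyses`
#'   (character vector of `"mean_rates"`, `"vm_stats"`, `"fano"`,
#'   `"correlations"`, `"tuning_correlations"`, `"factor_analysis"`,
#'   `"bump"`, `"timescales"`), and `analysis_params`.
#' @param out_dir optional directory; if given, tidy CSV outputs and the
#'   resolved config (YAML) are written there.
#' @return list with `config`, `sim` (the `ssn_sim` object) and
#'   `analyses` (named list of analysis results).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  arch <- build_architecture(config$architecture$type,
                             if (is.null(config$architecture$params)) list()
                             else config$architecture$params)
  if (config$architecture$type == "spiking_ssn")
    stop("run_experiment drives rate models; use simulate_spiking() directly")
  segs <- config$protocol
  durations <- vapply(segs, function(s) s$duration_ms, 1)
  hs <- lapply(segs, arch$input)
  protocol <- stimulus_protocol(durations, hs,
                                contrast = vapply(segs, function(s)
                                  if (is.null(s$c)) NA_real_ else s$c, 1))
  g <- function(name, default) if (is.null(config[[name]])) default else config[[name]]
  analyses <- g("analyses", character(0))
  ap <- g("analysis_params", list())
  gp <- function(name, default) if (is.null(ap[[name]])) default else ap[[name]]
  needs_counts <- any(c("fano", "correlations", "tuning_correlations",
                        "factor_analysis") %in% analyses)
  record <- g("record", c(if ("bump" %in% analyses) "V",
                          if (any(c("vm_stats", "timescales", "mean_rates") %in% analyses)) "trial_stats"))
  sim <- integrate_network(arch$net, protocol, arch$noise,
                           dt = g("dt", 0.1), seed = g("seed", 1L),
                           n_trials = g("n_trials", 1L),
                           record = record,
                           record_dt = g("record_dt", 1),
                           rate_bin_ms = if (needs_counts || !is.null(config$rate_bin_ms))
                             g("rate_bin_ms", 100) else NULL,
                           V_init = g("V_init", "rest"),
                           init_sd = g("init_sd", 1))
  res <- list()
  burn <- gp("burn_in_ms", 0)
  if (needs_counts) {
    use_bins <- which(sim$bin_times > burn)
    counts <- poisson_counts(sim$lambda[use_bins, , , drop = FALSE],
                             seed = g("seed", 1L) + 1000L)
  }
  if ("mean_rates" %in% analyses || "vm_stats" %in% analyses) {
    keep <- sim$times > burn
    is_E <- arch$net$is_E
    vm <- sim$trial_mean[keep, , drop = FALSE]
    vv <- sim$trial_var[keep, , drop = FALSE]
    fpV <- colMeans(vm)
    res$vm_stats <- data.frame(
      population = c("E", "I"),
      mean_V = c(mean(fpV[is_E]), if (any(!is_E)) mean(fpV[!is_E]) else NA),
      sd_V = c(sqrt(mean(vv[, is_E])), if (any(!is_E)) sqrt(mean(vv[, !is_E])) else NA))
    if ("mean_rates" %in% analyses) {
      rbar <- colMeans(eval_nonlinearity(arch$net$nl, vm))
      res$mean_rates <- data.frame(
        population = c("E", "I"),
        rate = c(mean(rbar[is_E]), if (any(!is_E)) mean(rbar[!is_E]) else NA))
    }
  }
  if ("fano" %in% analyses) {
    per_bin <- lapply(seq_len(dim(counts)[1]), function(b)
      fano_and_correlations(t(counts[b, , ]), mean_min = gp("mean_min", 0.01)))
    res$fano <- data.frame(
      neuron = seq_len(dim(counts)[2]),
      fano = rowMeans(sapply(per_bin, function(s) s$fano)))
    res$fano_mean <- mean(vapply(per_bin, function(s) s$fano_mean, 1))
  }
  if (any(c("correlations", "tuning_correlations", "factor_analysis") %in% analyses)) {
    pooled <- do.call(rbind, lapply(seq_len(dim(counts)[1]), function(b) t(counts[b, , ])))
    stats <- fano_and_correlations(pooled, mean_min = gp("mean_min", 0.01))
    if ("correlations" %in% analyses) res$correlations <- stats
    if ("tuning_correlations" %in% analyses)
      res$tuning_correlations <- tuning_averaged_correlations(
        stats$corr, arch$net$theta,
        theta_stim = gp("theta_stim", 0), split = gp("split", 45),
        n_bins = gp("corr_bins", 12))
    if ("factor_analysis" %in% analyses) {
      nc <- normalized_counts(pooled, mean_min = gp("mean_min", 0.01))
      res$factor_analysis <- factor_analysis(nc, k = gp("k", 3),
                                             mode = gp("fa_mode", "eigen"))
    }
  }
  if ("bump" %in% analyses) {
    keep <- sim$times > burn
    e_idx <- which(arch$net$is_E)
    res$bump <- bump_fit(sim$V[keep, e_idx, , drop = FALSE],
                         arch$net$theta[e_idx], arch$net$nl)
  }
  if ("timescales" %in% analyses) {
    pv <- rowMeans(sim$trial_var)
    on_off <- cumsum(durations)
    res$timescales <- variability_timescales(
      pv, sim$times, t_on = on_off[1], t_off = on_off[2],
      baseline_window = gp("baseline_window", c(on_off[1] / 2, on_off[1])),
      plateau_window = gp("plateau_window", c(mean(on_off[1:2]), on_off[2])))
    res$var_trajectory <- data.frame(time_ms = sim$times, var = pv)
  }
  out <- list(config = config, sim = sim, analyses = res)
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  invisible(out)
}

#' Write experiment outputs as tidy CSV files
#'
#' Writes one CSV per analysis product plus the resolved configuration
#' (YAML, including the seed) for provenance; identical configurations
#' produce byte-identical files.
#'
#' @param result a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    paths <<- c(paths, path)
  }
  a <- result$analyses
  if (!is.null(a$vm_stats)) wr(a$vm_stats, "vm_stats")
  if (!is.null(a$mean_rates)) wr(a$mean_rates, "mean_rates")
  if (!is.null(a$fano)) wr(a$fano, "fano")
  if (!is.null(a$tuning_correlations)) wr(a$tuning_correlations, "tuning_correlations")
  if (!is.null(a$bump)) wr(a$bump$series, "bump_series")
  if (!is.null(a$var_trajectory)) wr(a$var_trajectory, "var_trajectory")
  if (!is.null(a$correlations))
    wr(data.frame(neuron = seq_along(a$correlations$fano),
                  fano = a$correlations$fano,
                  mean_count = a$correlations$mean_count), "count_stats")
  if (!is.null(a$factor_analysis))
    wr(data.frame(neuron = seq_along(a$factor_analysis$shared_var),
                  shared_var = a$factor_analysis$shared_var,
                  private_var = a$factor_analysis$private), "factor_analysis")
  yaml::write_yaml(result$config, file.path(dir, "config.yaml"))
  invisible(c(paths, file.path(dir, "config.yaml")))
}

#' Synthetic orientation-tuned spike-count fixture
#'
#' Generates a trial-by-unit spike-count dataset with the structure of an
#' awake-monkey V1 orientation experiment (a synthetic stand-in; no real
#' data involved): around 100 units with circular-Gaussian orientation
#' tuning, several orientation conditions, and Poisson counts optionally
#' modulated by a rank-1 shared gain (to give super-Poisson, correlated
#' variability for factor-analysis recovery tests).
#'
#' @param n_units number of units.
#' @param orientations stimulus orientations (degrees on the 180-degree
#'   circle).
#' @param n_trials trials per orientation.
#' @param window_ms count window (ms).
#' @param f0_range,fm_range,kappa_range uniform ranges for the tuning
#'   parameters (baseline 1/s, modulation 1/s, concentration).
#' @param gain_sd standard deviation of the shared multiplicative gain
#'   (0 = pure Poisson; parametric model only).
#' @param model `"parametric"` (tuning curves + Poisson with optional
#'   shared gain) or `"ring_ssn"` (doubly stochastic Poisson counts from
#'   simulated ring-SSN rates; `n_units` is then the 100 ring units and
#'   a spontaneous condition is included).
#' @param seed integer seed.
#' @return list with `counts` (array `orientations x trials x units`),
#'   `orientations`, `truth` (data.frame of ground-truth tuning
#'   parameters, parametric model), `gain` (matrix of shared gains),
#'   `window_ms`; for `"ring_ssn"` additionally `spont_counts`
#'   (`trials x units`) and `theta` (unit ring angles).
#' @export
generate_fixture <- function(n_units = 100,
                             orientations = seq(0, 157.5, by = 22.5),
                             n_trials = 50, window_ms = 500,
                             f0_range = c(0.2, 1), fm_range = c(8, 30),
                             kappa_range = c(1.5, 3), gain_sd = 0,
                             model = c("parametric", "ring_ssn"),
                             seed = 1L) {
  model <- match.arg(model)
  if (model == "ring_ssn") return(ring_ssn_fixture(orientations, n_trials, seed))
  set.seed(seed)
  truth <- data.frame(
    unit = seq_len(n_units),
    f0 = stats::runif(n_units, f0_range[1], f0_range[2]),
    fm = stats::runif(n_units, fm_range[1], fm_range[2]),
    kappa = stats::runif(n_units, kappa_range[1], kappa_range[2]),
    theta_pref = stats::runif(n_units, 0, 180))
  n_ori <- length(orientations)
  rate <- sapply(seq_len(n_units), function(i)
    truth$f0[i] + truth$fm[i] *
      exp(truth$kappa[i] * (cos(2 * (orientations - truth$theta_pref[i]) * pi / 180) - 1)))
  # rate: n_ori x n_units
  gain <- matrix(pmax(1 + gain_sd * stats::rnorm(n_ori * n_trials), 0),
                 n_ori, n_trials)
  counts <- array(0L, c(n_ori, n_trials, n_units))
  for (o in seq_len(n_ori)) for (tr in seq_len(n_trials))
    counts[o, tr, ] <- stats::rpois(n_units, gain[o, tr] * rate[o, ] * window_ms / 1000)
  list(counts = counts, orientations = orientations, truth = truth,
       gain = gain, window_ms = window_ms)
}

# Counts from simulated ring-SSN rates: one 100 ms window per trial after
# a 600 ms settle, per orientation condition at full contrast, plus a
# spontaneous (zero-contrast) condition. Orientations are on the
# 180-degree circle; the ring angle is twice the orientation.
ring_ssn_fixture <- function(orientations, n_trials, seed) {
  geom <- ring_geometry(50, 50)
  net <- build_ring_ssn(geom)
  noise <- ring_noise_cov(geom)
  run_counts <- function(cc, theta_stim, sd) {
    h <- ring_input(geom, c = cc, theta_stim = theta_stim)
    sim <- integrate_network(net, stimulus_protocol(700, list(h)), noise,
                             dt = 0.1, seed = sd, n_trials = n_trials,
                             record = character(0), rate_bin_ms = 100)
    t(poisson_counts(sim$lambda[7, , , drop = FALSE], seed = sd + 1)[1, , ])
  }
  counts <- array(0L, c(length(orientations), n_trials, net$N))
  for (o in seq_along(orientations))
    counts[o, , ] <- run_counts(1, 2 * orientations[o], seed + o)
  list(counts = counts, orientations = orientations,
       spont_counts = run_counts(0, 0, seed),
       theta = net$theta, window_ms = 100)
}

#' Random-parameter robustness sweep of the two-population SSN
#'
#' Draws network parameters uniformly within user-supplied brackets,
#' checks linear stability of the fixed point at the largest input, and
#' summarizes the input dependence of E-population voltage variability
#' (peak location and height of `sd(V_E)(h)` from the linearized
#' covariance, and the firing rates at the peak).
#'
#' @param brackets named list of length-2 numeric ranges for any of the
#'   [build_two_pop()] parameters (e.g. `W_EE`, `W_EI`, `k`, `sigma_0E`).
#'   Collapsed brackets (equal endpoints) pin a parameter.
#' @param n_draws number of parameter draws.
#' @param h_grid input grid (mV) over which variability is traced.
#' @param seed integer seed.
#' @return data.frame with one row per draw: the drawn parameters,
#'   `stable` (at `max(h_grid)`), `h_peak`, `sd_peak`, `rate_E_peak`,
#'   `rate_I_peak` (`NA` for unstable draws).
#' @export
parameter_sweep <- function(brackets, n_draws = 100,
                            h_grid = seq(0, 20, by = 0.5), seed = 1L) {
  set.seed(seed)
  draws <- as.data.frame(lapply(brackets, function(b)
    stats::runif(n_draws, b[1], b[2])))
  out <- cbind(draws, stable = NA, h_peak = NA_real_, sd_peak = NA_real_,
               rate_E_peak = NA_real_, rate_I_peak = NA_real_)
  for (d in seq_len(n_draws)) {
    m <- tryCatch(do.call(build_two_pop, as.list(draws[d, , drop = FALSE])),
                  error = function(e) NULL)
    if (is.null(m)) { out$stable[d] <- FALSE; next }
    res <- tryCatch({
      fp_max <- fixed_point(m$net, max(h_grid))
      if (!attr(fp_max, "stable")) stop("unstable at max input")
      sds <- vapply(h_grid, function(h)
        sqrt(linearized_covariance(m$net, m$noise, h)[1, 1]), 1)
      pk <- which.max(sds)
      fp <- fixed_point(m$net, h_grid[pk])
      r <- eval_nonlinearity(m$net$nl, fp)
      list(h = h_grid[pk], sd = sds[pk], rE = r[1], rI = r[2])
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res)) { out$stable[d] <- FALSE; next }
    out$stable[d] <- TRUE
    out$h_peak[d] <- res$h; out$sd_peak[d] <- res$sd
    out$rate_E_peak[d] <- res$rE; out$rate_I_peak[d] <- res$rI
  }
  out
}
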