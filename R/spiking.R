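#' Spiking SSN specification
#'
#' Sparse random E/I connectivity for the stochastically spiking SSN.
#' Each neuron draws exactly `p_E * N_E` excitatory and `p_I * N_I`
#' inhibitory presynaptic partners uniformly at random; realized synapses
#' have efficacy `J_ij = W_ab / (tau_syn * p_b * N_b)` (with `tau_syn` in
#' seconds), so that for matched population rates the mean recurrent
#' input per population equals the reduced two-population model's `W r`.
#'
#' @param N_E,N_I population sizes.
#' @param p_E,p_I connection probabilities (E and I presynaptic).
#' @param W_EE,W_IE,W_EI,W_II reduced-model weight magnitudes (mV s).
#' @param tau_syn synaptic time constant (ms).
#' @param delay axonal delay (ms).
#' @param tau_E,tau_I,k,n,V0,Vrest membrane and nonlinearity parameters
#'   as in [build_two_pop()].
#' @param seed seed fixing the realized connectivity.
#' @return an object of class `spiking_net` containing the sparse
#'   efficacy matrix `J` (mV, signed) and all parameters.
#' @export
build_spiking_ssn <- function(N_E = 4000, N_I = 1000, p_E = 0.1, p_I = 0.4,
                              W_EE = 1.25, W_IE = 1.2, W_EI = 0.65, W_II = 0.5,
                              tau_syn = 2, delay = 0.5,
                              tau_E = 20, tau_I = 10,
                              k = 0.3, n = 2, V0 = -70, Vrest = -70,
                              seed = 1L) {
  set.seed(seed)
  N <- N_E + N_I
  K_E <- round(p_E * N_E)
  K_I <- round(p_I * N_I)
  tau_syn_s <- tau_syn / 1000
  Wmag <- rbind(E = c(E = W_EE, I = W_EI), I = c(E = W_IE, I = W_II))
  is_E <- c(rep(TRUE, N_E), rep(FALSE, N_I))
  ii <- vector("list", N); jj <- vector("list", N); xx <- vector("list", N)
  for (i in seq_len(N)) {
    post <- if (is_E[i]) "E" else "I"
    pre_E <- sample.int(N_E, K_E)
    pre_I <- N_E + sample.int(N_I, K_I)
    jj[[i]] <- c(pre_E, pre_I)
    ii[[i]] <- rep(i, K_E + K_I)
    xx[[i]] <- c(rep(Wmag[post, "E"] / (tau_syn_s * p_E * N_E), K_E),
                 rep(-Wmag[post, "I"] / (tau_syn_s * p_I * N_I), K_I))
  }
  J <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(N, N))
  structure(list(N_E = N_E, N_I = N_I, N = N, J = J,
                 p_E = p_E, p_I = p_I, K_E = K_E, K_I = K_I,
                 tau_syn = tau_syn, delay = delay,
                 tau = ifelse(is_E, tau_E, tau_I), Vrest = Vrest,
                 nl = nonlinearity("powerlaw", k = k, n = n, V0 = V0),
                 is_E = is_E, seed = seed),
            class = "spiking_net")
}

#' @export
print.spiking_net <- function(x, ...) {
  cat(sprintf("<spiking_net> %d E + %d I neurons, in-degree %d E / %d I, tau_syn = %g ms, delay = %g ms\n",
              x$N_E, x$N_I, x$K_E, x$K_I, x$tau_syn, x$delay))
  invisible(x)
}

#' Simulate the stochastically spiking SSN
#'
#' Event-based simulation of one or more trials. At every Euler step each
#' neuron emits a spike as a Bernoulli draw with probability
#' `dt * r(V_i)` (rates from the threshold power law). Spikes enter
#' exponentially decaying synaptic traces after the axonal delay
#' (implemented as a ring buffer of `delay/dt` steps, exact exponential
#' decay between events), and the traces drive the membrane dynamics with
#' the same OU input-noise machinery as the rate model.
#'
#' @param spec a [build_spiking_ssn()] object.
#' @param protocol an [stimulus_protocol()] object.
#' @param noise an [noise_spec()] object (typically
#'   [uniform_noise_cov()] with `rho = 0.2`), or `NULL`.
#' @param dt Euler step (ms); aborts if `dt * r` can exceed 0.2 anywhere.
#' @param seed integer seed.
#' @param n_trials number of trials (simulated sequentially; trial `t`
#'   uses sub-seed `seed + t - 1`).
#' @param record_dt recording resolution for Vm (ms); `NA` disables Vm
#'   recording.
#' @param record_neurons indices of neurons whose Vm is recorded
#'   (default: all).
#' @return an object of class `spiking_sim` with `spikes` (a list per
#'   trial of two-column `data.frame`s `neuron`, `time_ms`), recorded
#'   `V` (`n_rec x length(record_neurons) x n_trials`), and metadata.
#' @export
simulate_spiking <- function(spec, protocol, noise = NULL, dt = 0.1,
                             seed = 1L, n_trials = 1L,
                             record_dt = 1, record_neurons = NULL) {
  N <- spec$N
  seg <- protocol_segments(protocol, N, dt)
  n_tot <- sum(seg$n_steps)
  d_steps <- max(1L, round(spec$delay / dt))
  dec_syn <- exp(-dt / spec$tau_syn)
  dt_tau <- dt / spec$tau
  rec_on <- !is.na(record_dt)
  if (rec_on) {
    rec_every <- round(record_dt / dt)
    n_rec <- n_tot %/% rec_every
    if (is.null(record_neurons)) record_neurons <- seq_len(N)
    V_arr <- array(NA_real_, c(n_rec, length(record_neurons), n_trials))
  } else V_arr <- NULL
  has_noise <- !is.null(noise)
  if (has_noise) {
    L <- noise_factor(noise)
    a_ou <- exp(-dt / noise$tau_noise)
    b_ou <- sqrt(1 - a_ou^2)
  }
  Jt <- Matrix::t(spec$J)   # column access = outgoing synapses of a neuron
  spikes <- vector("list", n_trials)
  for (trial in seq_len(n_trials)) {
    set.seed(seed + trial - 1L)
    V <- rep(spec$Vrest, N)
    a_syn <- numeric(N)
    eta <- if (has_noise) drop(L %*% stats::rnorm(N)) else numeric(N)
    buf <- vector("list", d_steps)   # spike ids due at step s: slot (s-1) %% d + 1
    sp_id <- vector("list", 2048); sp_t <- vector("list", 2048); n_ev <- 0L
    step <- 0L; rec_idx <- 0L
    for (s_i in seq_along(seg$n_steps)) {
      h <- seg$h[[s_i]]
      for (kk in seq_len(seg$n_steps[[s_i]])) {
        step <- step + 1L
        slot <- (step - 1L) %% d_steps + 1L
        # deliver spikes emitted delay ago
        due <- buf[[slot]]
        a_syn <- a_syn * dec_syn
        if (length(due)) a_syn[due] <- a_syn[due] + 1
        rec_in <- as.numeric(spec$J %*% a_syn)
        V <- V + dt_tau * ((spec$Vrest - V) + h + eta + rec_in)
        r <- eval_nonlinearity(spec$nl, V)
        p <- r * dt / 1000
        if (max(p) > 0.2)
          stop("spike probability guard violated: dt * r > 0.2; reduce dt")
        fired <- which(stats::runif(N) < p)
        buf[[slot]] <- fired   # will be delivered d_steps later
        if (length(fired)) {
          n_ev <- n_ev + 1L
          if (n_ev > length(sp_id)) { length(sp_id) <- 2L*n_ev; length(sp_t) <- 2L*n_ev }
          sp_id[[n_ev]] <- fired
          sp_t[[n_ev]] <- rep(step * dt, length(fired))
        }
        if (has_noise)
          eta <- a_ou * eta + b_ou * drop(L %*% stats::rnorm(N))
        if (rec_on && step %% rec_every == 0L) {
          rec_idx <- rec_idx + 1L
          V_arr[rec_idx, , trial] <- V[record_neurons]
        }
      }
    }
    spikes[[trial]] <- data.frame(neuron = unlist(sp_id[seq_len(n_ev)]),
                                  time_ms = unlist(sp_t[seq_len(n_ev)]))
    rec_idx <- 0L
  }
  structure(list(spec = spec, protocol = protocol, dt = dt, seed = seed,
                 n_trials = n_trials, spikes = spikes, V = V_arr,
                 record_dt = record_dt, record_neurons = record_neurons,
                 times = if (rec_on) seq_len(dim(V_arr)[1]) * record_dt else NULL),
            class = "spiking_sim")
}

#' @export
print.spiking_sim <- function(x, ...) {
  n_sp <- vapply(x$spikes, nrow, 1L)
  cat(sprintf("<spiking_sim> %d neurons, %d trial(s), %g ms; %s spikes/trial (mean)\n",
              x$spec$N, x$n_trials, x$protocol$total,
              format(mean(n_sp), digits = 4)))
  invisible(x)
}

#' Local field potential proxy
#'
#' The momentary population-averaged membrane potential of a designated
#' population (default: all recorded neurons), a standard coarse proxy
#' for the LFP.
#'
#' @param V a `time x neurons` matrix or `time x neurons x trials` array
#'   of membrane potentials (mV).
#' @param neurons optional column indices over which to average.
#' @return a vector (or `time x trials` matrix) of LFP values (mV).
#' @export
lfp_proxy <- function(V, neurons = NULL) {
  if (length(dim(V)) == 3) {
    if (!is.null(neurons)) V <- V[, neurons, , drop = FALSE]
    apply(V, c(1, 3), mean)
  } else {
    if (!is.null(neurons)) V <- V[, neurons, drop = FALSE]
    rowMeans(V)
  }
}

#' Bin spikes into trial-by-neuron count matrices
#'
#' @param sim a `spiking_sim` object.
#' @param bin_ms bin width (ms).
#' @param t_start,t_end window to bin (ms; defaults to the full trial).
#' @return an array `n_bins x N x n_trials` of spike counts.
#' @export
bin_spikes <- function(sim, bin_ms = 100, t_start = 0, t_end = NULL) {
  if (is.null(t_end)) t_end <- sim$protocol$total
  edges <- seq(t_start, t_end, by = bin_ms)
  n_bins <- length(edges) - 1
  N <- sim$spec$N
  out <- array(0L, c(n_bins, N, sim$n_trials))
  for (tr in seq_len(sim$n_trials)) {
    sp <- sim$spikes[[tr]]
    sp <- sp[sp$time_ms > t_start & sp$time_ms <= t_end, ]
    if (!nrow(sp)) next
    b <- findInterval(sp$time_ms, edges, left.open = TRUE, rightmost.closed = TRUE)
    b[b < 1] <- 1L; b[b > n_bins] <- n_bins
    tab <- table(factor(b, levels = seq_len(n_bins)), factor(sp$neuron, levels = seq_len(N)))
    out[, , tr] <- as.integer(tab)
  }
  out
}

#' Doubly stochastic Poisson spike counts from rate trajectories
#'
#' Draws spike counts `~ Poisson(integral r dt)` per neuron, trial and
#' bin, independent across neurons given the rates. Used to relate the
#' rate models to spike-count statistics.
#'
#' @param lambda expected counts: an array `n_bins x N x n_trials` (e.g.
#'   the `lambda` element of an [integrate_network()] result).
#' @param seed integer seed.
#' @return integer array with the same dimensions as `lambda`.
#' @export
poisson_counts <- function(lambda, seed = 1L) {
  set.seed(seed)
  if (any(lambda < 0)) stop("negative expected counts")
  out <- array(stats::rpois(length(lambda), lambda), dim(lambda))
  dimnames(out) <- dimnames(lambda)
  out
}
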