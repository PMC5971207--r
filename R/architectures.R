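#' Circular-Gaussian profile
#'
#' `exp((cos(delta) - 1) / ell^2)` with the angular difference `delta`
#' given in degrees on the full circle and the length scale `ell`
#' converted from degrees to radians before squaring (the expression is
#' only dimensionally consistent with `ell` in radians; length scales
#' quoted in degrees, e.g. 45 or 60, are converted here).
#'
#' @param delta_deg angular difference(s), degrees.
#' @param ell_deg length scale, degrees.
#' @return profile value(s) in `(0, 1]`.
#' @export
circ_gaussian <- function(delta_deg, ell_deg) {
  ell <- ell_deg * pi / 180
  exp((cos(delta_deg * pi / 180) - 1) / ell^2)
}

#' Ring geometry
#'
#' Evenly spaced preferred angles on the full circle `[0, 360)` degrees
#' (a direction variable; orientation readouts halve all angles). For an
#' E/I ring the two populations are co-located: each angle hosts one E
#' and one I unit.
#'
#' @param N_E,N_I unit counts per population (`N_I = 0` for
#'   single-population rings). When both are positive they must be equal.
#' @param ell_syn,ell_noise,ell_stim length scales (degrees) of the
#'   connectivity, noise-correlation and stimulus-tuning profiles.
#' @return an object of class `ring_geometry` with `theta` of length
#'   `N_E + N_I` (E units first).
#' @export
ring_geometry <- function(N_E, N_I = 0, ell_syn = 45, ell_noise = 60,
                          ell_stim = 60) {
  if (N_I > 0 && N_E != N_I)
    stop("E and I ring populations must be co-located (N_E == N_I)")
  n_loc <- max(N_E, N_I)
  ang <- seq(0, 360, length.out = n_loc + 1)[seq_len(n_loc)]
  theta <- c(if (N_E > 0) ang, if (N_I > 0) ang)
  structure(list(N_E = N_E, N_I = N_I, theta = theta, angles = ang,
                 ell_syn = ell_syn, ell_noise = ell_noise,
                 ell_stim = ell_stim),
            class = "ring_geometry")
}

#' Reduced two-population SSN
#'
#' The two-unit network of one excitatory and one inhibitory population
#' with the standard parameter set: `W_EE = 1.25`, `W_IE = 1.2`,
#' `W_EI = 0.65`, `W_II = 0.5` mV s, `tau_E = 20`, `tau_I = 10` ms,
#' threshold-quadratic nonlinearity (`k = 0.3`, `n = 2`, `V0 = -70` mV),
#' and uncorrelated OU noise with `sigma_0E = 0.2`, `sigma_0I = 0.1` mV
#' and `tau_noise = 50` ms. The noise variances carry the scaling
#' `sigma_a^2 = sigma_0a^2 (1 + tau_a / tau_noise)` so that without
#' recurrence the stationary Vm standard deviation is exactly `sigma_0a`.
#'
#' @param W_EE,W_IE,W_EI,W_II weight magnitudes (mV s), all non-negative.
#' @param tau_E,tau_I membrane time constants (ms).
#' @param k,n,V0 nonlinearity gain, exponent, threshold.
#' @param Vrest resting potential (mV).
#' @param sigma_0E,sigma_0I effective noise amplitudes (mV).
#' @param tau_noise noise correlation time (ms).
#' @return `list(net, noise)`; unit 1 is E, unit 2 is I.
#' @export
build_two_pop <- function(W_EE = 1.25, W_IE = 1.2, W_EI = 0.65, W_II = 0.5,
                          tau_E = 20, tau_I = 10,
                          k = 0.3, n = 2, V0 = -70, Vrest = -70,
                          sigma_0E = 0.2, sigma_0I = 0.1, tau_noise = 50) {
  if (any(c(W_EE, W_IE, W_EI, W_II) < 0))
    stop("weight magnitudes must be non-negative (signs are applied internally)")
  W <- matrix(c(W_EE, W_IE, -W_EI, -W_II), 2, 2)
  net <- network_spec(1, 1, W, tau = c(tau_E, tau_I), Vrest = Vrest,
                      nl = nonlinearity("powerlaw", k = k, n = n, V0 = V0),
                      dale = TRUE)
  s2 <- c(sigma_0E^2 * (1 + tau_E / tau_noise),
          sigma_0I^2 * (1 + tau_I / tau_noise))
  noise <- noise_spec(tau_noise, diag(s2), factor = diag(sqrt(s2)))
  list(net = net, noise = noise)
}

#' Ring SSN connectivity
#'
#' Builds the E/I ring network: synaptic weights follow a circular
#' Gaussian of the angular distance with length scale `ell_syn`, then
#' each row is rescaled within each of the four E/I quadrants so that the
#' summed incoming E and I weights onto every E and I neuron match the
#' two-population targets `(W_EE, W_IE, -W_EI, -W_II)` exactly. The
#' resulting matrix obeys Dale's law.
#'
#' @param geometry an [ring_geometry()] object with `N_I > 0`.
#' @param W_EE,W_IE,W_EI,W_II target incoming-weight sums (mV s,
#'   magnitudes).
#' @inheritParams build_two_pop
#' @return an [network_spec()] object with `theta` attached.
#' @export
build_ring_ssn <- function(geometry,
                           W_EE = 1.25, W_IE = 1.2, W_EI = 0.65, W_II = 0.5,
                           tau_E = 20, tau_I = 10,
                           k = 0.3, n = 2, V0 = -70, Vrest = -70) {
  stopifnot(inherits(geometry, "ring_geometry"), geometry$N_I > 0)
  th <- geometry$theta
  N <- length(th)
  G <- circ_gaussian(outer(th, th, `-`), geometry$ell_syn)
  is_E <- c(rep(TRUE, geometry$N_E), rep(FALSE, geometry$N_I))
  W <- matrix(0, N, N)
  targets <- rbind(E = c(E = W_EE, I = -W_EI), I = c(E = W_IE, I = -W_II))
  for (post in c("E", "I")) {
    rows <- if (post == "E") which(is_E) else which(!is_E)
    for (pre in c("E", "I")) {
      cols <- if (pre == "E") which(is_E) else which(!is_E)
      blk <- G[rows, cols, drop = FALSE]
      rs <- rowSums(blk)
      if (any(rs == 0)) stop("ring rescale failed: zero profile row")
      W[rows, cols] <- blk * (targets[post, pre] / rs)
    }
  }
  nl <- nonlinearity("powerlaw", k = k, n = n, V0 = V0)
  network_spec(geometry$N_E, geometry$N_I, W, tau = ifelse(is_E, tau_E, tau_I),
               Vrest = Vrest, nl = nl, theta = th, dale = TRUE)
}

#' Ring stimulus input
#'
#' `h_i = b + c * A_max * exp((cos(theta_i - theta_stim) - 1)/ell_stim^2)`:
#' a constant baseline plus a contrast-scaled circular-Gaussian bump
#' centered on the stimulus angle. E and I units at the same angle are
#' driven identically.
#'
#' @param geometry an [ring_geometry()] object.
#' @param c contrast in `[0, 1]`.
#' @param b baseline (mV).
#' @param A_max maximal modulation at 100% contrast (mV).
#' @param theta_stim stimulus angle (degrees).
#' @return input vector `h` (mV), length `N_E + N_I`.
#' @export
ring_input <- function(geometry, c = 1, b = 2, A_max = 20, theta_stim = 0) {
  stopifnot(c >= 0, c <= 1, b >= 0, A_max >= 0)
  b + c * A_max * circ_gaussian(geometry$theta - theta_stim, geometry$ell_stim)
}

#' Ring noise covariance
#'
#' `Sigma_ij = sigma_i sigma_j exp((cos(theta_i - theta_j) - 1)/ell_noise^2)`
#' with per-unit amplitudes `sigma_i = sigma_0 * sqrt(1 + tau_i/tau_noise)`
#' determined by population identity: input-noise correlations decay with
#' tuning difference.
#'
#' @param geometry an [ring_geometry()] object.
#' @param sigma_0E,sigma_0I effective amplitudes (mV) per population
#'   (`sigma_0I` ignored when `N_I = 0`).
#' @param tau_E,tau_I membrane time constants (ms) entering the amplitude
#'   scaling.
#' @param tau_noise noise correlation time (ms).
#' @return an [noise_spec()] object.
#' @export
ring_noise_cov <- function(geometry, sigma_0E = 1, sigma_0I = 0.5,
                           tau_E = 20, tau_I = 10, tau_noise = 50) {
  is_E <- c(rep(TRUE, geometry$N_E), rep(FALSE, geometry$N_I))
  sig <- ifelse(is_E,
                sigma_0E * sqrt(1 + tau_E / tau_noise),
                sigma_0I * sqrt(1 + tau_I / tau_noise))
  C <- circ_gaussian(outer(geometry$theta, geometry$theta, `-`),
                     geometry$ell_noise)
  Sigma <- outer(sig, sig) * C
  noise_spec(tau_noise, Sigma)
}

#' Uniform (compound-symmetric) noise covariance
#'
#' `Sigma_ij = sigma^2 * (delta_ij (1 - rho) + rho)`: equal variances with
#' a common pairwise correlation `rho`, as used by the spiking SSN. The
#' square-root factor is supplied in closed form, so sampling costs
#' `O(N)` per step instead of an `N x N` eigendecomposition.
#'
#' @param N number of units.
#' @param sigma_noise common amplitude (mV).
#' @param rho pairwise correlation in `[0, 1]`.
#' @param tau_noise noise correlation time (ms).
#' @return an [noise_spec()] object.
#' @export
uniform_noise_cov <- function(N, sigma_noise, rho = 0.2, tau_noise = 50) {
  stopifnot(rho >= 0, rho <= 1)
  Sigma <- sigma_noise^2 * ((1 - rho) * diag(N) + rho)
  a <- sigma_noise * sqrt(1 - rho)
  b <- sigma_noise * sqrt(1 - rho + N * rho)
  L <- matrix((b - a) / N, N, N)
  diag(L) <- diag(L) + a
  noise_spec(tau_noise, Sigma, factor = L)
}

#' Multi-attractor ring network
#'
#' The marginally stable single-population ring:
#' `W_ij = (Wbar + W_Delta cos(theta_i - theta_j)) / N` with all-negative
#' weights at the standard parameters, rectified-saturating nonlinearity
#' `r(V) = gmax * tanh(k * max(V, 0))`, and spatially correlated OU noise.
#' The cosine interaction puts the network in the marginally stable
#' regime: spontaneous activity is a bump of activity at an arbitrary,
#' slowly drifting position, and the stimulus
#' `h_i = b + c (1 - A + A cos(theta_i - theta_stim))` pins it.
#'
#' Two conventions fix the quoted parameters. `gmax` is taken as the
#' maximal firing rate 100 1/s with gain `k = 0.1` per mV, which makes
#' `Wbar * gmax` of order mV as the dynamics require. The coupling is
#' normalized by `N`, so `Wbar = -40/gmax = -0.4` mV s is the summed
#' incoming weight per neuron — the same scale as the ring SSN's
#' incoming-weight sums, to which this model is matched. (The
#' un-normalized per-connection reading would make total inhibition
#' exceed the cosine modulation more than a hundredfold, pinning summed
#' network rates near 5 1/s and admitting no activity bump at all.)
#'
#' @param N number of units.
#' @param gmax maximal rate (1/s); `Wbar = -40/gmax`, `W_Delta = 33/gmax`
#'   (mV s) by default.
#' @param Wbar,W_Delta summed and cosine-modulated incoming connectivity
#'   (mV s).
#' @param k nonlinearity gain (1/mV).
#' @param tau_m membrane time constant (ms).
#' @param sigma_0,ell_noise,tau_noise noise parameters as in the ring SSN.
#' @param b input baseline (mV); `A` modulation depth.
#' @return `list(net, noise, geometry, input)` where `input(c, theta_stim)`
#'   builds the mean-input vector.
#' @export
build_multiattractor <- function(N = 100, gmax = 100, Wbar = -40 / gmax,
                                 W_Delta = 33 / gmax, k = 0.1, tau_m = 10,
                                 sigma_0 = 0.15, ell_noise = 60,
                                 tau_noise = 50, b = 2, A = 0.1) {
  geometry <- ring_geometry(N, 0, ell_noise = ell_noise, ell_stim = ell_noise)
  th <- geometry$theta
  W <- (Wbar + W_Delta * cos(outer(th, th, `-`) * pi / 180)) / N
  if (any(W >= 0))
    stop("multi-attractor construction: expected all-inhibitory weights")
  nl <- nonlinearity("rect_tanh", k = k, gmax = gmax)
  net <- network_spec(N, 0, W, tau = tau_m, Vrest = 0, nl = nl, theta = th)
  sig <- sigma_0 * sqrt(1 + tau_m / tau_noise)
  C <- circ_gaussian(outer(th, th, `-`), ell_noise)
  noise <- noise_spec(tau_noise, sig^2 * C)
  input <- function(c = 0, theta_stim = 0) {
    b + c * (1 - A + A * cos((th - theta_stim) * pi / 180))
  }
  list(net = net, noise = noise, geometry = geometry, input = input)
}

#' Chaotic random rate network
#'
#' The classic deterministic chaotic network: `N` units with
#' `tau_m dV/dt = -V + h + W r(V)`, `r(V) = tanh(V)`, and i.i.d. Gaussian
#' weights `W_ij ~ N(0, sigma_W^2 / N)`. With `sigma_W = 2` the
#' autonomous dynamics are chaotic; a constant input
#' `h_i = c * cos(phi_i)` with fixed random phases `phi_i` suppresses the
#' chaos for large enough `c`. Across-trial variability comes from random
#' initial conditions, not injected noise.
#'
#' @param N number of units.
#' @param sigma_W weight standard-deviation scale.
#' @param tau_m membrane time constant (ms).
#' @param seed seed fixing the weights and phases.
#' @return `list(net, phases, input)` where `input(c)` builds the
#'   mean-input vector.
#' @export
build_chaotic <- function(N = 2000, sigma_W = 2, tau_m = 10, seed = 1L) {
  set.seed(seed)
  W <- matrix(stats::rnorm(N * N, sd = sigma_W / sqrt(N)), N, N)
  phases <- stats::runif(N, 0, 2 * pi)
  net <- network_spec(N, 0, W, tau = tau_m, Vrest = 0,
                      nl = nonlinearity("tanh"))
  input <- function(c = 0) c * cos(phases)
  list(net = net, phases = phases, input = input)
}
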