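---
title: "Stimulus modulation of neural variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus modulation of neural variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnvar)
```

## The scientific problem

Cortical activity is variable, and a stimulus reliably quenches that
variability — particularly the component *shared* across neurons — in a
stimulus-tuned way. Three dynamical regimes have been proposed to explain
this: wandering among multiple attractors that a stimulus pins to one;
chaotic rate dynamics that a strong input entrains; and the regime this
package centres on, stochastic fluctuations around a *single*,
stimulus-dependent attractor of a loosely balanced excitatory-inhibitory
network with supralinear neurons — the stochastic stabilized supralinear
network (SSN). `ssnvar` implements all three as a single simulator family
plus the analysis battery used to discriminate them: Fano factors, noise
correlations by tuning similarity, LFP spectra and Vm–LFP coherence,
factor analysis of normalized spike counts, bump-kinetics covariance
decomposition, and variability-suppression timescales.

## Models

### Voltage dynamics and nonlinearities

All rate models share the form

$$\tau_i \frac{dV_i}{dt} = -V_i + V_{\mathrm{rest}} + h_i(t) + \eta_i(t)
  + \sum_j W_{ij}\, r(V_j),$$

with membrane potentials in mV, rates in 1/s and weights in mV·s. The SSN
uses the threshold power law $r(V) = k\lfloor V - V_0\rfloor_+^n$
(defaults $k = 0.3$ mV$^{-2}$s$^{-1}$, $n = 2$, $V_0 = -70$ mV): because
it is supralinear and non-saturating, the slope $f'(\bar V)$ — and with it
the *effective connectivity* $W^{\mathrm{eff}}_{ij} = W_{ij} f'(\bar V_j)$
— grows with stimulus drive. Weak drive leaves amplifying E–I interactions
(balanced amplification) dominant and variability high; strong drive
recruits dominant inhibitory feedback and quenches it. The multi-attractor
ring uses the rectified saturating form $g_{\max}\tanh(k\lfloor V\rfloor_+)$,
and the chaotic network the plain $\tanh(V)$.

### Input noise

$\eta(t)$ is a multivariate Ornstein–Uhlenbeck process with correlation
time $\tau_{\mathrm{noise}} = 50$ ms and spatial covariance
$\Sigma^{\mathrm{noise}}$; its stationary law is
$\mathcal N(0, \Sigma^{\mathrm{noise}})$ with autocovariance
$\Sigma_{ij} e^{-|\Delta t|/\tau_{\mathrm{noise}}}$. Amplitudes carry the
scaling $\sigma_\alpha = \sigma_{0,\alpha}\sqrt{1 + \tau_\alpha /
\tau_{\mathrm{noise}}}$ so that an *uncoupled* unit has stationary Vm
standard deviation exactly $\sigma_{0,\alpha}$ — the closed form used as a
test oracle throughout. The two-population model uses uncorrelated noise
($\sigma_{0,E} = 0.2$, $\sigma_{0,I} = 0.1$ mV); the ring models use a
circular-Gaussian correlation profile with length 60°
($\sigma_{0,E} = 1$, $\sigma_{0,I} = 0.5$ mV — the parameter table's
merged columns are parsed this way, the unique reading consistent with
$\sigma_{0,I} = \sigma_{0,E}/2$); the spiking model uses uniform
correlation $\rho = 0.2$.

### Architectures

* **Two-population SSN** (`build_two_pop()`): one E and one I unit,
  $W_{EE} = 1.25$, $W_{IE} = 1.2$, $W_{EI} = 0.65$, $W_{II} = 0.5$ mV·s,
  $\tau_E = 20$, $\tau_I = 10$ ms.
* **Ring SSN** (`build_ring_ssn()`): 50 co-located E/I pairs on the full
  360° circle (a direction variable; orientation readouts halve all
  angles). Weights follow a circular Gaussian of angular distance with
  $\ell_{\mathrm{syn}} = 45°$, then every row of every E/I quadrant is
  rescaled so incoming-weight sums match the two-population values
  exactly; Dale's law holds by construction. The stimulus is a baseline
  $b = 2$ mV plus a contrast-scaled circular-Gaussian bump
  ($A_{\max} = 20$ mV, $\ell_{\mathrm{stim}} = 60°$), identical for E and
  I cells at the same angle. All length scales quoted in degrees are
  converted to radians inside
  $\exp[(\cos\Delta\theta - 1)/\ell^2]$ — the expression is only
  dimensionally consistent in radians.
* **Spiking SSN** (`build_spiking_ssn()`): 4000 E / 1000 I neurons by
  default, each drawing exactly $p_E N_E = 400$ excitatory and
  $p_I N_I = 400$ inhibitory partners; efficacies
  $J_{ij} = W_{\alpha\beta}/(\tau_{\mathrm{syn}} p_\beta N_\beta)$ make
  mean recurrent input match the reduced model at equal rates. Spikes are
  Bernoulli per step with probability $dt\, r(V_i)$ (a guard aborts if
  that ever exceeds 0.2), filtered by 2 ms exponential synapses after a
  0.5 ms delay implemented as a ring buffer; spikes do not reset the
  emitting neuron's own Vm.
* **Multi-attractor ring** (`build_multiattractor()`): 100 units,
  all-inhibitory coupling
  $W_{ij} = (\bar W + W_\Delta \cos(\theta_i - \theta_j))/N$ with
  $\bar W = -0.4$, $W_\Delta = 0.33$ mV·s. Two conventions in the quoted
  parameters were genuinely open and are fixed as follows. First,
  $g_{\max}$ is the maximal rate, 100 1/s, with gain $k = 0.1$ /mV.
  Second, the coupling is normalized by $N$, making $\bar W$ the *summed*
  incoming weight — the same scale as the ring SSN's row sums, to which
  this model is deliberately matched. The alternative per-connection
  reading makes total inhibition exceed the cosine modulation more than a
  hundredfold; total network rate is then pinned near 5 s$^{-1}$ summed,
  the spatial Vm modulation (< 0.02 mV) drowns in the noise, no activity
  bump can exist, and spontaneous Fano factors sit at 1.0 instead of the
  1.5 this model is calibrated to produce. Under the adopted reading the
  network shows the intended marginal regime: a spontaneous bump at an
  arbitrary, slowly drifting position (peak rates ~15 1/s) that a
  stimulus pins and that re-forms elsewhere after stimulus offset.
* **Chaotic network** (`build_chaotic()`): 2000 units,
  $W_{ij} \sim \mathcal N(0, \sigma_W^2/N)$ with $\sigma_W = 2$,
  deterministic dynamics; across-trial variability comes from random
  initial conditions, and the input $h_i = c\cos\phi_i$ with fixed random
  phases suppresses the chaos at large $c$. The step amplitudes used in
  the timescale experiments, $c \in \{0.6, 0.9, 1.3\}$, were chosen once
  to span roughly 45–90% variance suppression and are recorded in the
  shipped configurations.

## Numerical choices

Integration is forward Euler at $dt = 0.1$ ms (configurable, with a hard
precondition $dt \le \tau_{\min}/10$); the chaotic network, noiseless with
$\tau_m = 10$ ms, is run at $dt = 1$ ms. The OU noise is advanced by its
*exact* exponential propagator, so its stationary distribution is correct
at any step size; $\Sigma^{\mathrm{noise}}$ is factorized by symmetric
eigendecomposition with eigenvalues below $-10^{-10}$ an error and small
negative ones clipped to zero (the compound-symmetric covariance gets a
closed-form factor instead). Trials are integrated jointly as an
$N \times n_{\mathrm{trials}}$ state; all randomness descends from a
single integer seed with a documented draw order, so every simulation is
bit-reproducible given `(seed, dt, n_trials)` — the package's determinism
contract, enforced by byte-identity tests on experiment outputs. A guard
aborts integration (naming the offending step) if any $|V|$ exceeds
1000 mV.

Fixed points are found by relaxation (noiseless integration at a large
stable step, default) or damped Newton, cross-checked against each other
to $10^{-6}$ mV; stability is certified by the Jacobian
$A = T^{-1}(W^{\mathrm{eff}} - I)$. The stationary covariance of
linearized fluctuations solves a continuous Lyapunov equation on the
augmented state $(\delta V, \eta)$; the block structure is exploited (the
noise block is $\Sigma$ exactly, the cross block a linear solve, the
voltage block an $N \times N$ Lyapunov equation solved via the Jacobian's
eigendecomposition), and the solver is validated against the uncoupled
closed form and weak-noise Monte-Carlo. Note what this linearization *is
not*: at the variability peak ($h \approx 2$ mV) fluctuations are large
relative to the suprathreshold voltage and the quadratic nonlinearity
makes the true (Monte-Carlo) variance deviate from the linear prediction
by ~15%, and at $h = 0$ the fixed point sits exactly at the
rectification threshold, where the one-sided slope is zero and rectified
excursions produce ~17% more variance than the feedforward value the
linearization returns. The package treats the linearized covariance as a
fast qualitative tool (e.g. for parameter sweeps); quantitative claims
are made by simulation.

## Analyses

Spike counts for the rate models are doubly stochastic Poisson draws from
$\int r\,dt$ per 100 ms bin. Fano factors are across-trial
variance/mean per neuron; neurons with mean count below 0.01 are flagged
and excluded from population means rather than divided. Normalized counts
follow $\tilde c_{ik} = c_{ik}/\langle c_{ik}\rangle_k$ (the printed
formula; the exact identity is then
$\mathrm{Var}(\tilde c_i)\,\langle c_i\rangle = \mathrm{Fano}_i$, and the
package tests that identity rather than the loose claim that the variance
*is* the Fano factor, which would require dividing by the square root of
the mean). Factor analysis is by direct eigendecomposition (shared = best
rank-$k$ approximation, exact diagonal additivity) or by EM on the
likelihood with a $10^{-6}$ ridge. Correlation-by-tuning curves classify
pairs at 45° of preferred-*orientation* difference (90° on the direction
ring) and bin by stimulus orientation relative to the pair-average
preference; the reported modulation depth is the peak-to-trough range of
the binned curve, an estimator whose noise floor shrinks with the amount
of data pooled — the acceptance checks therefore pool 20 stationary
100 ms bins across 500 trials.

The bump fit models the threshold-referenced E-population voltage as
$a\,\exp[(\cos(\theta_i - \mu) - 1)/\sigma^2]$ per stored time step;
$(\mu, \sigma)$ minimize the squared residual (Nelder–Mead, warm-started,
initialized at the circular centre of mass and spread) while $a$ enforces
a constant total population rate — for the power law that constraint has
a closed-form solution. Referencing voltages to $V_0$ is the natural
baseline for a power-law population and is the convention throughout. The
captured fraction pools variance jointly over cells, time and trials
(the across-cell structure of the bump counts as Vm variability); a
stricter fluctuation-only fraction (per-cell temporal means removed,
necessarily lower) is reported alongside it, as the pooling convention is
genuinely ambiguous.
Covariance templates are outer products of the analytic location
derivative and the numerically differentiated width derivative (which
inherits the amplitude constraint), scaled by the fitted series'
variances and covariance.

Welch spectra use 1 s Hann windows at 50% overlap with per-segment linear
detrending; coherence averages cross- and auto-spectra over segments and
then coherence curves over cells. Suppression/recovery timescales are
half-crossing times of the across-trial variance between baseline and
plateau, with latency (the last time the trajectory stays inside a
±2 SE baseline band) discarded, mirroring how such time constants are
read off experimental trajectories.

## What the synthetic fixtures emulate — and what they do not

`generate_fixture()` produces orientation-tuned spike-count datasets with
the *shape* of an awake-monkey V1 session (~100 tuned units, several
orientations, tens to hundreds of trials): parametric circular-Gaussian
tuning with Poisson counts and an optional rank-1 multiplicative gain
(for factor-analysis recovery), or counts driven by actual ring-SSN
simulations. The parametric defaults are chosen so most units pass the
standard selection (OTI ≥ 0.75, evoked rate ≥ 1 1/s), emulating a
*post-selection* population. These fixtures are synthetic stand-ins: they
contain no recording artifacts, no isolation contamination, no slow
session drift, and their noise is exactly Poisson-conditional-on-rate, so
tests passing on them demonstrate correctness of the estimators, not
fidelity of real V1 statistics.

## Desk-scale problem sizes

Network sizes are never reduced below their defining values (the spiking
model offers a 1000 E / 250 I preset with rescaled $J$ for routine
testing). Trial counts and durations in the test suite are the package's
desk-scale choices: 300–500 trials of 1.5–5 s for the rate models,
100–200 trials for the chaotic network (at $N = 600$ in the test suite,
$N = 2000$ in the acceptance script), chosen so Monte-Carlo error is
comfortably inside each scientific tolerance. The acceptance script's
runs state their sizes in its console log.

## Known limitations

* The linearized covariance is quantitatively biased near threshold and
  at the variability peak (see above); the moment-closure analytics that
  would fix this are deliberately out of scope.
* At reduced spiking-network scale, synaptic efficacies are several times
  larger than at full scale, so rate-dependent shot noise dominates
  single-cell (private) Vm variance; shared-variability conclusions are
  therefore drawn on smoothed population signals.
* The multi-attractor parameter conventions are fixed by phenomenology
  (bump regime, spontaneous Fano ≈ 1.5) as described; other readings of
  the published table are dynamically inconsistent but cannot be ruled
  out typographically.
* Gamma-band spiking fluctuations and conductance-based mechanisms are
  not modelled.

## A minimal example

```{r example, eval = FALSE}
tp <- build_two_pop()
sapply(c(0, 2, 15), function(h) {
  fp <- fixed_point(tp$net, h)
  c(h = h, r_E = eval_nonlinearity(tp$net$nl, fp)[1],
    sd_E = sqrt(linearized_covariance(tp$net, tp$noise, h)[1, 1]))
})
```
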