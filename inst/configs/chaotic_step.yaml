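# Chaotic rate network: across-trial variance suppression by a step input
# and its slow recovery. Amplitudes c in {0.6, 0.9, 1.3} span roughly
# 45-90% variance suppression; run once per amplitude.
name: chaotic_step
architecture:
  type: chaotic
  params: {N: 2000, sigma_W: 2, tau_m: 10, seed: 1}
protocol:
  - {duration_ms: 600, c: 0}
  - {duration_ms: 500, c: 0.9}
  - {duration_ms: 1200, c: 0}
n_trials: 200
dt: 1
seed: 1
V_init: random
init_sd: 1
record_dt: 5
analyses: [timescales]
analysis_params:
  baseline_window: [300, 600]
  plateau_window: [850, 1100]
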