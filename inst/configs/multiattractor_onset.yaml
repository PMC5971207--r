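# Multi-attractor ring: across-trial variance around stimulus onset/offset
# (the transient variance increase and slow suppression). The stimulus is
# held twice as long as in the SSN runs so suppression is visible past the
# onset transient.
name: multiattractor_onset
architecture:
  type: multi_attractor
  params: {}
protocol:
  - {duration_ms: 800, c: 0}
  - {duration_ms: 1000, c: 1, theta_stim: 0}
  - {duration_ms: 700, c: 0}
n_trials: 200
dt: 0.1
seed: 1
V_init: random
init_sd: 2
analyses: [timescales]
analysis_params:
  baseline_window: [400, 800]
  plateau_window: [1300, 1800]
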