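# Ring SSN at 100% contrast: spike-count statistics, tuning-resolved
# correlations, factor analysis and bump kinetics in the evoked state.
name: ring_evoked
architecture:
  type: ring_ssn
  params: {}
protocol:
  - {duration_ms: 1600, c: 1, theta_stim: 0}
n_trials: 200
dt: 0.1
seed: 1
rate_bin_ms: 100
record_dt: 10
analyses: [fano, correlations, tuning_correlations, factor_analysis, bump]
analysis_params:
  burn_in_ms: 600
  k: 3
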