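# Two-population SSN: spontaneous -> weak -> strong drive, population
# Vm statistics and mean rates (the input-sweep phenomenology at three
# operating points).
name: two_pop_step
architecture:
  type: two_pop
  params: {}
protocol:
  - {duration_ms: 2000, h: 0}
  - {duration_ms: 2000, h: 2}
  - {duration_ms: 2000, h: 15}
n_trials: 200
dt: 0.1
seed: 1
analyses: [vm_stats, mean_rates]
analysis_params:
  burn_in_ms: 500
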