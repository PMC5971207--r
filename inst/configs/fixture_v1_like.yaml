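# Synthetic orientation-tuned spike-count dataset (V1-session shape) for
# the `ssnvar fixture` command: 100 well-tuned units, 8 orientations,
# Poisson counts with a rank-1 shared gain.
n_units: 100
orientations: [0, 22.5, 45, 67.5, 90, 112.5, 135, 157.5]
n_trials: 50
window_ms: 500
gain_sd: 0.2
seed: 1
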