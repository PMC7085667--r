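# Example pipeline configuration: synthetic day-period cohort, all analysis
# cells, one model per period. Quote "N" (bare N is a YAML boolean).
cohort:
  preset: hs
  seed: 1
  coupling: 2
periods: [morning, afternoon, night]
modes: [ALL5, EN, "N"]
features: [spectrum_raw, spectrum_variability]
n_restarts: 50
curve_k_max: 8
seed: 1
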