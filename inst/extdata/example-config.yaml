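# Example simulation configuration: 60-min nap run, 12 regions,
# three groups of regions with staggered oscillation onset lags.
seed: 1
duration_s: 3600
n_regions: 12
onset_lag_s: [0, 0, 0, 0, 10, 10, 10, 10, 20, 20, 20, 20]
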