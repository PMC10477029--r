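# SYNTHETIC example coefficient set for the CHOPROP-style logistic alarm.
# These numbers are package inventions for demonstration and testing: the
# published coefficient set is NOT distributed with this package and must
# be transcribed from its source publication into a file like this one.
# Scaling: GA in weeks, BW in grams, weight-gain rate in g/day.
intercept: 10.0
beta_ga: -0.35
beta_bw: -0.004
beta_wg: -0.12
cutoff: 0.014
ga_scale: weeks
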