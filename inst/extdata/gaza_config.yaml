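# Default run configuration: packaged survey summaries, the three standard
# population scenarios, 100,000 Monte Carlo iterations.
summary: packaged
scenarios:
  - adult_male
  - adult_female
  - child_1_3
n_iter: 100000
seed: 42
percentiles: [25, 50, 75, 90, 95, 99]
censor_policy: half
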