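# Two-strategy single-generation experiment at moderate competition:
# 150 individuals, half fixed at K = 0.25 and half at K = 0.85, in the
# 3-food mild environment. Run with
#   nutlat run exp2-config.yaml --out results/
experiment: single-generation
environment:
  preset: 3-food-mild
  intake_target: [500, 500]
c: [0.683, 0.767]
eta: 25
n_ind: 150
phi: 2
mu: 2
n_iterations: 500
composition:
  k_low: 0.25
  k_high: 0.85
  prop_high: 0.5
n_replicates: 30
seed: 1
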