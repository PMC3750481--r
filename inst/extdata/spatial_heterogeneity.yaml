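# Spatially heterogeneous labeling efficacy: two thirds of divisions take
# up the full label, one third only half of it.
name: spatial_heterogeneity
population:
  n_init: 1000
  alpha: 0.1
  beta: 0.1
  S: 20
phases:
  - duration: 10
    efficacy:
      variant: mixture
      weights: [0.33333333333333331, 0.66666666666666663]
      means: [0.5, 1]
      sds: [0.05, 0.05]
output:
  eval_times: [2, 4, 6, 8, 10]
  grid: {min: -0.5, max: 1.5, n_points: 2001}
  l_theta: [0.1]
  sample_size: 0
seed: 1
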