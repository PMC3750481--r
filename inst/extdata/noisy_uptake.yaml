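# Noisy label uptake: 10 d uplabeling with normally distributed efficacy,
# then 10 d delabeling (zero efficacy; content halves per division).
name: noisy_uptake
population:
  n_init: 1000
  alpha: 0.1        # division rate per day
  beta: 0.1         # death rate per day
  S: 20             # truncation order per phase
phases:
  - duration: 10
    efficacy: {variant: normal, mean: 1, sd: 0.2}
  - duration: 10
    efficacy: {variant: dirac, location: 0}
output:
  eval_times: [2, 4, 6, 8, 10, 12, 14, 16, 18, 20]
  grid: {min: -0.5, max: 1.5, n_points: 2001}
  l_theta: [0.1]
  sample_size: 0
seed: 1
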