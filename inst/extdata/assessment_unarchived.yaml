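# Unarchived-unretrieved Bayesian assessment configuration: only the
# retrieved stratum was stored; recall/specificity/prevalence estimated
# by the latent false-negative Gibbs sampler.
mode: unarchived
n1: 82205
n2: 3872370
precision_interval: [0.949, 0.961]
priors:
  prevalence: {mean: 0.010, interval: [1.0e-6, 0.031]}
  recall: {mean: 0.667, interval: [0.340, 0.954]}
  specificity: {mean: 0.733, interval: [0.474, 0.962]}
n_cycles: 100000
burn_in: 10000
seed: 1
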