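# Classical (gold-standard coding) assessment configuration: the coded
# stratified sample of the e-cigarette case study.
mode: classical
counts: {a: 4176, b: 197, c: 20, d: 6285}
sampling:
  retrieved_sampled: 4373
  unretrieved_sampled: 6305
  retrieved_population: 82205
  unretrieved_population: 3872370
seed: 1
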