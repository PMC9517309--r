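# Quick-start pipeline configuration: two small synthetic cohorts,
# default angle definitions, clustering 9 -> 4 stages, default seat.
seed: 7
cohorts:
  elderly:
    n_subjects: 6
    noise_sd: 0.005
    interval: 0.25
    seed: 8
  control:
    n_subjects: 6
    noise_sd: 0.005
    interval: 0.25
    seed: 9
clustering:
  k: 9
  coarse: 4
  seed: 10
importance:
  split: 0.75
  hidden_units: 4
  n_perm: 20
  seed: 11
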