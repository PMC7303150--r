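# Example end-to-end scenario for runScenario(): two groups at the stall
# rates typical of 11-month APP/PS1 and wild-type cohorts, scored by a
# simulated 60-player crowd with a calibrated stopping threshold.
seed: 2024
players:
  n: 60
  shape1: 8
  shape2: 2
crowd:
  q: 0.25
  base_rate: 0.01
  threshold: calibrate
groups:
  APP-PS1-NC:
    stall_rate: 0.02
    n_stacks: 3
    segments_per_stack: 1500
    composition:
      leukocyte: 0.86
      platelet: 0.05
      rbc_only: 0.09
  WT-NC:
    stall_rate: 0.006
    n_stacks: 3
    segments_per_stack: 1500
    composition:
      leukocyte: 0.0
      platelet: 0.5
      rbc_only: 0.5
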