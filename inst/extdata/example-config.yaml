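# Example pipeline configuration: simulate an 8-participant trial under the
# default design and analyze it end to end. Sections mirror the package
# modules; omitted keys take the documented defaults and unknown keys are
# rejected.
design:
  total_days: 28
  baseline_min: 7
  baseline_max: 14
cohort:
  n: 8
  mode: balanced_permutation
  seed: 42
  model:
    d: 0.8          # standardized phase effect
    gamma: 5        # acute pre->post exercise drop, slider units
preprocessing:
  min_obs_per_phase: 3
  b_phase_value: post_else_pre
inference:
  alternative: less
  method: auto      # exhaustive when the joint space fits, else Monte Carlo
  R: 5000
  seed: 11
output:
  dir: jitai-analysis
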