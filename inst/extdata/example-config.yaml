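# Example pipeline configuration for read_run_config().
# Top-level keys mirror the arguments of run_config(); defaults reproduce the
# study protocol (23 participants, all regressors, all interpolations).
seed: 0
n_participants: 5
families:
  - ridge
  - random_forest
interpolations:
  - linear
  - nearest
folds: 5
threshold_uv: 75
smooth_window_s: 30
synth:
  artifact_prob: 0.02
  survey_jitter_prob: 0.1
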