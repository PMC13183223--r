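# Default pipeline parameters (the conventional values for this workflow).
# Input paths must be supplied by the caller; see ?readPipelineConfig.
thresholds:
  lfc: 0.5
  p: 0.05
  use_adjusted: false
filter:
  apply: false
  direct_only: true
  fit_top_frac: 0.2
overlap:
  B: 10000
  mode: all
centrality:
  top_k: 20
  score_min: 0.4
ml:
  n_folds: 5
  outer: 5
  inner: 5
  repeats: 100
  bootstrap_B: 1000
  max_runs: 1000
  alpha: 0.01
  gbt_rounds: 50
  num_trees: 300
grid:
  thresholds: [0.25, 0.5, 0.75, 1.0, 1.25, 1.5]
seed: 1
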