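# Demo pipeline configuration (see ?run_config for every field).
seed: 1
min_seizures: 10
min_ictal_len: 2
catalog_preset: default
move_threshold: 0.05
n_components: 3
ci_method: wald
leave_one_out: false
selection:
  n_trees_grid: [25, 50, 100]
  min_split_grid: [2, 4, 6]
  n_folds: 5
  n_selected: 5
  seed: 1
  fold_strategy: stratified_by_person
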