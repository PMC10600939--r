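# Example run configuration for run_all() / read_run_config().
# Fields mirror the arguments of run_config(); omitted fields keep
# their defaults.
width_tr: 22
step_tr: 1
dfc_method: sliding_window
discard_initial_volumes: 5
selection_mode: regression
selection_fraction: 0.01
k_neighbors: 100
tune: false
c_x: 0.7
c_y: 0.8
n_perm: 1000
n_boot: 1000
stability_threshold: 0.9
q_threshold: 0.05
seed: 1
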