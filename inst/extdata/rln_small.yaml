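# Small reactive lymph-node demonstration scenario.
# Run with: run_pipeline(system.file("extdata", "rln_small.yaml",
#                                    package = "lymphochemnet"),
#                        out_dir = "rln_small_out")
scenario: rLN
n_cells: 400
seed: 1
downsample_per_type: 20
n_subjects: 80
n_perm: 99
params:
  knn: 15
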