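# Example run configuration. Keys mirror the arguments of gfe_config();
# unknown keys are rejected. All landmark indices are 0-based (0-99).
selection: user_dependent
window_size: 10
window_stride: 1
label_rule: majority      # majority | last | all
normalization: zscore     # zscore | none
seed: 1
classifier_params:
  num.trees: 300
# Override the derived pair/triple lists explicitly if desired:
# pair_list:
#   - [18, 22]
#   - [24, 31]
# triple_list:
#   - [18, 22, 24]
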