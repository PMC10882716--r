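# demo pipeline configuration: synthetic quarter, default study conditions
out_dir: pipeline_out
synth:
  n_cases: 3000
  drug_share: 0.10
target_soc: "10037175"
min_count: 5
z: 1.96
quantile_type: 7
comparator: full
seed: 42
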