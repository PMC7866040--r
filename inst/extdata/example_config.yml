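# Example pipeline configuration. Keys mirror pipeline_config().
contrast: lung_adk
co2_threshold: 2.0
alpha: 0.05
nfolds: 50
grid_size: 50
bootstrap_B: 200
min_sensitivity: 85
seed: 17
# cohort_path: cohort.csv   # omit to simulate from the default spec
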