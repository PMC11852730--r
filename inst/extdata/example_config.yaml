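# Example pipeline configuration (see read_pipeline_config()).
# A reduced cohort for a quick demonstration run; drop the `simulate`
# overrides to reproduce the full 106-lesion study conditions.
simulate:
  n_wt: 10
  n_mt: 8
  roi_shape: [16, 16, 8]
  spacing_mm: [1, 1, 3]
  n_reseg: 6
preprocess:
  normalize_scale: 100
  outlier_sigma: 3
  bin_width: 25
  target_spacing_mm: [1, 1, 1]
  bias_on: T2
filters:
  wavelet_family: coif1
  log_sigmas_mm: [3, 5]
extraction:
  use_filters: false
selection:
  icc_threshold: 0.85
  alpha: 0.05
  spearman_threshold: 0.9
  cv_folds: 5
  lambda_rule: min
seed: 1
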