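# Example pipeline configuration for a reduced synthetic cohort.
# All keys mirror pipeline_config() / cohort_design() arguments.
seed: 1
de_alpha: 0.05
corr_alpha: 0.05
vip_threshold: 1.0
search_strategy: exhaustive
design:
  n_ctrl: 9
  n_mci: 10
  n_ad: 9
  n_proteins: 600
  n_cluster1: 32
  n_cluster2: 27
  n_cluster3: 13
  n_corr_pos: 18
  n_corr_neg: 6
  effect_size: 0.8
  noise_sd: 0.5
  missing_rate: 0.05
  panel_size: 4
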