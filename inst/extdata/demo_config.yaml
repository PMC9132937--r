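# Demonstration configuration for the synthetic regional pipeline.
# Usage:
#   cfg <- pipeline_config_from_yaml(system.file("extdata",
#            "demo_config.yaml", package = "cibop"))
#   cfg$out_dir <- "demo_out"
#   res <- run_pipeline(cfg)
seed: 11
synthetic: true
preset: regional
synth:
  n_proteins: 600
  mice_per_group: 2
  tech_reps: 2
  frac_enriched: 0.10
  delta_enrich: 3.0
  frac_regional: 0.15
  delta_region: 2.5
  noise_sd: 0.5
filter:
  mode: min-valid-per-group
  k: 3
  group_col: genotype
impute:
  width: 0.3
  shift: 1.8
fc_enrich: 2
fc_core: 4
p_threshold: 0.05
z_threshold: 1.96
k_clusters: 5
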