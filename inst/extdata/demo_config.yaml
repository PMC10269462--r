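# Demonstration pipeline configuration (see ?run_pipeline and
# ?default_config for the full schema and defaults). Any omitted key keeps
# its default and is still recorded, resolved, in the run manifest.
seed: 1
scenario: default        # preset name; or provide input: {counts, taxonomy, metadata}
rarefy_depth: ~          # null = minimum sample total
network:
  rho_threshold: 0.8
  p_threshold: 0.05
  p_adjust: false
  min_prevalence: 3
  min_mean_relabund: 1.0e-4
modules:
  min_module_size: 5
robustness:
  fractions: [0.01, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5, 0.55, 0.6]
  n_reps: 20
permanova:
  n_perm: 999
hubs:
  top_fraction: 0.1
knockout:
  genus: Trichoderma
  modes: [remove, reduce]
  match_threshold: 0.5
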