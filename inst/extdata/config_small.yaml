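# Desk-scale run configuration (matches default_config())
simulation:
  n: 2000
  m: 3000
  n_chrom: 6
  maf_bounds: [0.05, 0.5]
  ld_block_size: 3
  ld_rho: 0.8
  bp_spacing: 10000
  genotype_seed: 11
  component_seed: 12
  external_seed: 13
  effect_seed: 14
  n_external: 8000
  external_traits: external_md
  exclusion_rate: 0.025
  missing_rate: 0
phenotypes:
  components: [recurrence, symptoms5, duration, impairment, persistence]
estimation:
  K_policy: sample_pre_exclusion
  n_blocks: 200
  jackknife_seed: 17
  ld_window_bp: 1000000
  exclude_region:
    chrom: 2
    start_bp: 2000000
    end_bp: 2200000
output:
  write_genotypes: false
  write_plink: false
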