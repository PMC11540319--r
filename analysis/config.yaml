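seed: 1
paths:
  output_dir: results
simulation:
  n_founders: 8
  n_sites: 5000
  group_split: [3, 5]
  d_between: 4000
  d_within: 15
  n_samples: 2000
  missing_rate_mean: 0.65
  missing_rate_sd: 0.08
  het_error_rate: 0.01
  chromosome: Y
  phewas:
    n_samples: 1000
    n_snps: 2000
    sibship_size: 10
    n_traits: 200
    heritability: 0.5
  expression:
    n_per_group: 100
    n_genes: 200
    dispersion: 0.1
    planted_gene: g50
    fold_change: 2
filters:
  haplotype:
    info_min: 0.9
    drop_maf_zero: true
    max_snp_missing: 0.25
    max_sample_missing: 0.50
association:
  reference_like_group: REF_GROUP
  fdr_level: 0.05
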