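#!/usr/bin/env Rscript
# Stage 1: simulate the founder panel and the noisy study population,
# and serialize both as VCF plus a truth table for downstream stages.
suppressPackageStartupMessages(library(nrhap))

cfg <- read_pipeline_config("analysis/config.yaml")
sim <- cfg$simulation
out <- cfg$paths$output_dir
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- simulate_founder_haplotypes(
  n_founders = sim$n_founders, n_sites = sim$n_sites,
  group_split = unlist(sim$group_split),
  d_between = sim$d_between, d_within = sim$d_within,
  chrom = sim$chromosome, seed = derive_seed(cfg$seed, "panel"))

pop <- simulate_population(
  panel, n_samples = sim$n_samples,
  missing_rate_mean = sim$missing_rate_mean,
  missing_rate_sd = sim$missing_rate_sd,
  het_error_rate = sim$het_error_rate,
  seed = derive_seed(cfg$seed, "population"))

write_vcf(panel, file.path(out, "founders.vcf"))
write_vcf(pop$matrix, file.path(out, "genotypes.vcf"))
write.table(pop$truth, file.path(out, "simulation_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

write_run_manifest(file.path(out, "01_simulate_manifest.json"), cfg,
  stages = list(simulate = list(
    founders = dim(panel$calls), population = dim(pop$matrix$calls))))
cat("wrote", nrow(pop$matrix$calls), "samples x",
    ncol(pop$matrix$calls), "sites to", out, "\n")
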