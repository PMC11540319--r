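#!/usr/bin/env Rscript
# Stage 3: build the haplotype phylogeny. Pairwise Hamming distances are
# computed on the founder panel and on a per-group subsample of the
# population, then summarized as neighbor-joining trees in Newick form.
suppressPackageStartupMessages(library(nrhap))

cfg <- read_pipeline_config("analysis/config.yaml")
out <- cfg$paths$output_dir
chrom <- cfg$simulation$chromosome

panel <- read_vcf(file.path(out, "founders.vcf"), chromosome = chrom)
d_founders <- hamming_distance_matrix(panel)
write_distance_matrix(d_founders, file.path(out, "founder_distances.tsv"))
tr <- neighbor_joining(d_founders, clamp_negative = TRUE)
write_newick(tr, file.path(out, "founder_tree.nwk"))

# a small per-group subsample of called samples, for a population-level tree
gm <- read_vcf(file.path(out, "genotypes.vcf"), chromosome = chrom)
gm <- mask_hemizygous_hets(gm)$matrix
asg <- read.delim(file.path(out, "haplogroup_assignments.tsv"))
set.seed(derive_seed(cfg$seed, "tree_subsample"))
pick <- unlist(lapply(c("REF_GROUP", "ALT_GROUP"), function(g) {
  ids <- asg$sample_id[asg$label == g]
  sample(ids, min(10, length(ids)))
}))
sub <- gm_subset(gm, samples = pick)
d_pop <- hamming_distance_matrix(sub)
tr_pop <- neighbor_joining(d_pop, clamp_negative = TRUE)
write_newick(tr_pop, file.path(out, "population_tree.nwk"))

write_run_manifest(file.path(out, "03_tree_manifest.json"), cfg,
  stages = list(
    founder_tree = list(n_taxa = nrow(d_founders$d),
                        n_negative_edges = attr(tr, "n_negative_edges")),
    population_tree = list(n_taxa = nrow(d_pop$d))))
cat("founder tree:", write_newick(tr), "\n")
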