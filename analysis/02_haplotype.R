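#!/usr/bin/env Rscript
# Stage 2: call haplogroups from the simulated VCF. Heterozygous calls on
# the hemizygous chromosome are masked as missing, the INFO filter is
# applied (the missingness stages are deliberately disabled here: sparse
# per-sample coverage is the regime haplogroup calling must tolerate),
# samples are assigned by majority allele, and per-group consensus
# haplotypes are matched back to the founder panel.
suppressPackageStartupMessages(library(nrhap))

cfg <- read_pipeline_config("analysis/config.yaml")
out <- cfg$paths$output_dir
chrom <- cfg$simulation$chromosome

gm <- read_vcf(file.path(out, "genotypes.vcf"), chromosome = chrom)
panel <- read_vcf(file.path(out, "founders.vcf"), chromosome = chrom)

masked <- mask_hemizygous_hets(gm)
flt <- apply_filter_cascade(masked$matrix,
  filter_config(info_min = cfg$filters$haplotype$info_min, stages = "INFO"))
write_filter_report(flt, file.path(out, "02_filter_report.tsv"))

asg <- assign_haplogroups(count_alleles(flt$matrix))
write_assignments(asg, file.path(out, "haplogroup_assignments.tsv"))

match_rows <- list()
for (g in c("REF_GROUP", "ALT_GROUP")) {
  cons <- consensus_genotypes(flt$matrix, asg, g)
  m <- match_founders(cons, panel)
  iv <- intragroup_variation(flt$matrix, asg, cons, g)
  write.table(iv$per_sample,
              file.path(out, paste0("intragroup_", tolower(g), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  match_rows[[g]] <- cbind(group = g, m$distances, tie = m$tie)
}
write.table(do.call(rbind, match_rows), file.path(out, "founder_matches.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

write_run_manifest(file.path(out, "02_haplotype_manifest.json"), cfg,
  stages = list(
    mask = list(masked_het_calls = masked$masked_count),
    filter = list(dims_in = flt$dims_in, dims_out = flt$dims_out),
    assignment = as.list(table(asg$label))))
cat("assignments:", paste(names(table(asg$label)), table(asg$label),
                          collapse = ", "), "\n")
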