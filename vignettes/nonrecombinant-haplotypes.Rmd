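---
title: "Haplogroups on nonrecombinant chromosomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplogroups on nonrecombinant chromosomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrhap)
```

## The scientific problem

Outbred heterogeneous stock (HS) rodent populations descend from a small
panel of inbred founder strains. Autosomes are recombinant mosaics of
founder haplotypes, but the Y chromosome and the mitochondrial genome are
inherited whole, without recombination, down the paternal and maternal
lines respectively. Every animal therefore carries one intact founder
haplotype on each nonrecombinant chromosome, and the population partitions
into a small number of *haplogroups* — clusters of near-identical
haplotypes descending from distinct founder lineages.

`nrhap` implements the full chain of analyses this structure invites:

1. call each sample's haplogroup from noisy, low-coverage imputed
   genotypes;
2. summarize each haplogroup by a consensus haplotype and match it back
   to the founder panel;
3. place haplotypes on a neighbor-joining tree built from pairwise
   Hamming distances;
4. test the haplogroup against many phenotypes (a PheWAS) with a mixed
   linear model that uses an autosomal genetic relationship matrix (GRM)
   to absorb family structure; and
5. test haplogroup effects on gene expression with rank-based statistics
   after trimmed-mean-of-M-values (TMM) normalization.

Because real deposited genotype archives are far too large to ship or
recompute here, the package pairs every analysis step with a synthetic
generator of known truth (`simulate_*`), and all validation is
property-based: the tests assert mathematical and statistical properties
of the code on simulated data. **No test asserts an empirical result that
the test itself does not compute** — published sample counts, haplogroup
sizes, or divergence figures from any particular dataset are never used
as expected values.

## Hemizygous genotypes and haplogroup calling

Y and MT loci are hemizygous: a heterozygous diploid call is biologically
impossible and can only be a genotyping or imputation artifact.
`mask_hemizygous_hets()` therefore converts every HET call to MISSING
before any downstream step, and `count_alleles()` refuses matrices that
still contain HETs.

Assignment is deliberately simple and transparent. With only two deeply
diverged clades, most informative sites are fixed differences, so a
sample's haplogroup is decided by a **strict majority** of its non-missing
calls: more reference alleles gives `REF_GROUP`, more alternate gives
`ALT_GROUP`, and an exact tie gives `UNASSIGNED` — ties are never broken
arbitrarily, and unassigned samples are excluded from consensus building
and association. This majority rule is what makes the caller robust to
the 50–80% per-sample missingness typical of low-coverage imputation: a
sample with only a few hundred called sites still yields an overwhelming
majority when the clades differ at thousands of positions.

The per-group **consensus haplotype** is the per-site modal non-missing
call among the group's members; a site with no calls, or an exact
REF/ALT tie, stays missing in the consensus. `match_founders()` compares
a consensus with each founder at the sites non-missing in both, reporting
normalized Hamming distances, the best-matching founder(s), and an
explicit tie flag. `intragroup_variation()` counts each sample's
mismatches against its own group's consensus, which is the natural
screen for intra-haplogroup variants or sample mix-ups.

An important workflow consequence: haplogroup calling runs the filter
cascade with the missingness stages *disabled* (INFO only). At realistic
missingness every variant exceeds any sensible per-variant missingness
threshold, and the majority rule is the mechanism that tolerates
sparsity; removing sparse variants first would simply delete the data.
The analysis drivers make this choice explicit via the cascade's stage
list.

## The filter cascade

`apply_filter_cascade()` runs up to four stages in a pinned order, each
recomputed on the current (already filtered) matrix:

| stage            | removes                                   | default threshold |
|------------------|-------------------------------------------|-------------------|
| `INFO`           | variants with imputation INFO below `info_min` | 0.9          |
| `MAF`            | variants with zero minor-allele count      | on                |
| `SNP_MISSING`    | variants with missing rate `>` `max_snp_missing` | 0.25       |
| `SAMPLE_MISSING` | samples with missing rate `>` `max_sample_missing` | 0.50     |

Thresholds are strict inequalities — a variant missing in exactly 25% of
samples survives. Allele counts treat a (not yet masked) HET as one
reference plus one alternate allele. Variants without an INFO score are
retained at the INFO stage rather than silently dropped.

The order is pinned because it matters: removing high-missingness
variants first can *rescue* samples that would otherwise fail the sample
missingness stage. The tests pin this with a four-line fixture whose
removals are hand-enumerated (one per stage) and with an order-swap
demonstration where running `SAMPLE_MISSING` first drops a sample that
the canonical order keeps. A related subtlety: enabling additional
*variant* stages can never increase the number of surviving variants
(each variant stage is a per-variant marginal test and the sample set is
unchanged until the final stage), but the number of surviving *samples*
can legitimately increase — that is the same rescue effect — so the
monotonicity property is asserted on variant counts.

## Distances and neighbor joining

`hamming_distance_matrix()` computes, for each pair of haplotypes, the
proportion of disagreeing sites among sites non-missing in both, and
records the number of comparable sites; a pair with no comparable site is
a hard, named error rather than a silent zero. `neighbor_joining()` wraps
the classical agglomerative algorithm (via `ape::nj`) after validating
symmetry and nonnegativity.

Two numerical points:

* On an *additive* distance matrix, neighbor joining is exact: the
  tree's path lengths reproduce the input distances to machine precision,
  and for three taxa the branch lengths have the closed form
  `a = (d_AB + d_AC − d_BC)/2` (cyclically). The tests assert both, and
  additionally compare the recovered topology against a brute-force
  least-squares search over all unrooted topologies.
* On noisy, non-additive input NJ can produce **negative branch
  lengths**. These are never hidden: the returned tree carries an
  `n_negative_edges` attribute, and `clamp_negative = TRUE` optionally
  sets them to zero while transferring the length to the adjacent edge so
  that path lengths through the pair are preserved where possible.

## Mixed-model PheWAS

Haplogroup membership is inherited down family lines, so it is inevitably
confounded with relatedness: siblings share both a father (hence a Y
haplogroup) and half their autosomes (hence phenotypic correlation).
Naive regression of a heritable trait on haplogroup is therefore
miscalibrated. The package follows the standard mixed-model strategy:

* `compute_grm()` builds the GRM `A[j,k] = mean_i (x_ij − 2p_i)(x_ik −
  2p_i) / (2p_i(1−p_i))`, averaging each pair over the SNPs non-missing
  in both members. `grm_snp_filters()` first applies missingness, MAF
  and Hardy–Weinberg screens (the HWE exact test can be restricted to a
  sex subset, e.g. females only, when male genotypes on a given
  chromosome are artifactual).
* `reml_variance_components()` fits `y = Xβ + g + e` with
  `g ~ N(0, σ_g² K)` by restricted maximum likelihood. One spectral
  decomposition of `K` reduces the problem to a one-dimensional profile
  over the ratio `γ = σ_g²/σ_e²`, optimized on the log scale over
  `log γ ∈ [−12, 8]` with the `γ = 0` boundary checked explicitly. An
  identity GRM makes the two components non-identifiable and is a named
  error, not a silent answer.
* `mlma_test()` performs the 1-df generalized-least-squares Wald test of
  the encoded haplotype with the null-model variance components held
  fixed — the convention of mainstream mixed-model association tools. A
  constant tested variant is flagged rather than assigned a p-value.
* `mlma_scan()` scans many traits, reusing a single eigendecomposition
  for all traits with the same missingness pattern, and attaches
  Benjamini–Hochberg q-values. `ols_scan()` is the deliberately naive
  comparator used to demonstrate inflation, summarized by
  `genomic_lambda()`.

Phenotypes are prepared by `preprocess_phenotype()`: residualize on
covariates by OLS, then map ranks to normal quantiles with the Blom
offset `(r − 3/8)/(n + 1/4)`, averaging ranks for ties. The rank-based
transform converges to the centered data in distribution's bulk, but
individual extreme order statistics retain O(1) sampling noise — a point
the tests respect by bounding central quantiles of the deviation rather
than its maximum. Haplotype is encoded `{0, 2}` like a homozygous
diploid dosage, so the fitted `beta` is *half* the haplogroup mean
difference.

## Expression

`tmm_normalize()` computes TMM scale factors (doubly trimmed log-ratio
means against a reference sample, delta-method precision weights) and
TMM-adjusted counts per million. The implementation is delegated to the
established edgeR routine; correctness is guarded by an *independent*
transcription of the published formula in the test suite, which must
agree to 1e-8 — the two routes are never collapsed into one call.

`de_scan()` compares expression between haplogroups with the
Mann–Whitney test (exact enumeration when both groups have ≤ 25 samples
and there are no ties, continuity-corrected normal approximation
otherwise), pooling BH correction across tissues by default with a
per-tissue option. Because the statistic is rank-based, it is invariant
under strictly monotone transforms of the normalized expression — a
property the tests verify directly. `xsnp_linear_scan()` runs
sex-stratified linear models of expression on X-SNP dosage, adding the
Y haplogroup as a covariate in the male stratum and requiring a minimum
number of minor-allele carriers per stratum.

## The synthetic generators: realism and limits

`simulate_founder_haplotypes()` builds a founder panel with two clades
separated by a fixed block of between-group differences (`d_between`)
plus per-founder private sites (`d_within`), at disjoint positions.
`simulate_population()` lets each sample inherit one founder haplotype
whole — by default with exactly one founder per clade carrying
population mass, at frequencies 0.633/0.367, mirroring the situation in
long-bred colonies where lineages of most founders have been lost. The
observation model is applied per call: a per-sample missing rate drawn
from a moment-matched Beta distribution (defaults: mean 0.65, sd 0.08,
i.e. the 50–80% regime of low-coverage imputation), a small HET error
rate (1%) standing in for imputation artifacts, and Beta-distributed
INFO scores.

`simulate_autosomal_dosages()` creates unrelated samples or full
sibships (four parental haplotypes, free recombination, so sibs have
expected genomic relationship 0.5); `sibship_haplogroups()` assigns
haplogroups *by family*, creating exactly the confounding the mixed
model must absorb. `simulate_phenotypes()` adds a polygenic term built
from standardized dosages, scaled to a chosen heritability, plus
optional haplotype and covariate effects. `simulate_expression()` draws
negative-binomial counts (variance `μ + φμ²`) with planted fold changes
and optional male-specific genes.

Limits worth stating plainly: founder haplotypes are iid site patterns,
not real linkage-disequilibrium structure; recombination in the sibship
model is free (no genetic map); missingness is independent across sites
given the per-sample rate, whereas real coverage is locally correlated;
and HET errors are uniform rather than concentrated at hard-to-impute
sites. These simplifications are fine for the properties being tested
(majority calling, calibration, power), but parameter estimates from
these generators should not be read as quantitative predictions for any
real colony.

All generator randomness flows from a single master seed through
`derive_seed(seed, label)`, so every stage is independently reproducible
and two runs with the same configuration are byte-identical.

## Problem sizes used in validation

The shipped validation exercises the pipeline at sizes chosen to be
large enough to be meaningful and small enough to run in minutes on one
CPU: haplogroup recovery on 8 founders × 5,000 sites × 2,000 samples;
MLMA calibration on 2,000 null traits at n = 1,000 in sibships of 10;
REML recovery over 50 replicates at n = 1,000; 100 null-PheWAS pipeline
replicates (n = 400, 40 traits each) and 100 planted differential
expression replicates (2-fold, 100 samples per group). These sizes are
the package's own validation choices, not properties of any dataset.

## Known limitations

* Only two haplogroups per chromosome are modelled end to end; the
  assignment rule generalizes to more clades only via repeated binary
  splits.
* The MLMA fixes variance components at their null-model estimates per
  trait (the usual computational shortcut); exact per-variant REML would
  be slower and changes little when single-variant effects are small.
* The HWE exact test assumes autosomal biallelic genotypes; for sex
  chromosomes it should be run on the appropriate sex subset, which the
  filter API supports but cannot decide for you.
* Negative NJ edge clamping redistributes length locally; it preserves
  total tree length but is still a heuristic repair of non-additivity.
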