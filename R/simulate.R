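#' Derive a reproducible sub-seed from a master seed
#'
#' Each simulated artifact draws from its own pseudo-random stream seeded
#' deterministically from a master seed and a label, so one artifact can
#' be regenerated without disturbing the others.
#'
#' @param master integer master seed
#' @param label character label of the artifact
#' @return integer seed below 2^31
#' @export
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

#' Simulate founder haplotypes for a nonrecombinant chromosome
#'
#' Builds one haplotype per founder strain over `n_sites` biallelic SNPs.
#' Founders are split into two haplogroups; `d_between` sites are fixed
#' differences between the groups and each founder carries `d_within`
#' private sites of its own, all at disjoint positions. Any cross-group
#' founder pair therefore differs at exactly
#' `d_between + 2 * d_within` sites and any within-group pair at
#' `2 * d_within` sites. This mirrors a population whose eight founders
#' fall into two clades (a reference-like clade and an alternate clade),
#' with modest private variation inside each clade.
#'
#' @param n_founders number of founder strains (default 8)
#' @param n_sites number of biallelic SNP sites (default 5000)
#' @param group_split integer vector of length 2 giving group sizes
#'   (default `c(3, 5)`: a small reference-like clade and a larger
#'   alternate clade)
#' @param d_between number of sites fixed-different between the groups
#' @param d_within number of private sites per founder
#' @param seed integer seed
#' @param chrom chromosome label for the variant table (default "Y")
#' @return a [geno_matrix()] with founders as samples (ids `F1..Fk`) and
#'   attributes `founder_groups` (named group label per founder, values
#'   REF_GROUP/ALT_GROUP), `between_sites`, `private_sites` (list)
#' @export
simulate_founder_haplotypes <- function(n_founders = 8, n_sites = 5000,
                                        group_split = c(3, 5),
                                        d_between = 4000, d_within = 15,
                                        seed = 1, chrom = "Y") {
  if (length(group_split) != 2 || sum(group_split) != n_founders)
    stop("group_split must be two counts summing to n_founders")
  if (d_between + n_founders * d_within > n_sites)
    stop("site budget exceeded: d_between + n_founders*d_within > n_sites")
  set.seed(derive_seed(seed, "founders"))
  founders <- paste0("F", seq_len(n_founders))
  groups <- rep(c("REF_GROUP", "ALT_GROUP"), group_split)
  names(groups) <- founders

  special <- sample.int(n_sites, d_between + n_founders * d_within)
  between <- special[seq_len(d_between)]
  private <- split(special[-seq_len(d_between)],
                   rep(founders, each = d_within))[founders]
  if (d_within == 0) private <- stats::setNames(rep(list(integer(0)), n_founders), founders)

  calls <- matrix(0L, n_founders, n_sites, dimnames = list(founders, NULL))
  calls[groups == "ALT_GROUP", between] <- 2L
  for (f in founders) {
    calls[f, private[[f]]] <- 2L - calls[f, private[[f]]]  # flip own private sites
  }
  variants <- data.frame(chrom = chrom, pos = seq_len(n_sites),
                         ref = "A", alt = "G",
                         info_score = NA_real_, stringsAsFactors = FALSE)
  gm <- geno_matrix(calls, variants)
  attr(gm, "founder_groups") <- groups
  attr(gm, "between_sites") <- sort(between)
  attr(gm, "private_sites") <- lapply(private, sort)
  gm
}

#' Simulate a low-coverage modern population from a founder panel
#'
#' Every sample inherits one founder haplotype in its entirety (no
#' recombination on Y/MT). The observation model emulates low-coverage
#' imputed genotypes: per sample a missingness rate is drawn from a Beta
#' distribution matched to `missing_rate_mean`/`missing_rate_sd`, and each
#' call is then emitted as the latent allele with probability
#' `1 - missing - het_error`, as a (biologically impossible) HET with
#' probability `het_error`, and MISSING otherwise. Per-variant imputation
#' INFO scores are drawn from `Beta(info_shape1, info_shape2)`.
#'
#' @param panel founder panel from [simulate_founder_haplotypes()]
#' @param n_samples number of modern samples
#' @param founder_frequencies probability per founder of contributing the
#'   chromosome; must sum to 1 and be named by (or aligned with) the
#'   panel's founders. The default gives the whole mass to one founder of
#'   each clade (frequencies 0.633 / 0.367), emulating a population where
#'   a single founder haplotype per clade persists.
#' @param missing_rate_mean,missing_rate_sd mean and sd of the per-sample
#'   missingness rate on \[0, 1\]
#' @param het_error_rate probability that a non-missing call is emitted HET
#' @param info_shape1,info_shape2 Beta parameters for per-variant INFO scores
#' @param female_fraction fraction of samples labelled female (default 0:
#'   a Y-chromosome cohort is all male)
#' @param seed integer seed
#' @return list: `matrix` (a [geno_matrix()]), `truth` (data frame:
#'   sample_id, founder, haplogroup, sex)
#' @export
simulate_population <- function(panel, n_samples = 2000,
                                founder_frequencies = NULL,
                                missing_rate_mean = 0.65, missing_rate_sd = 0.08,
                                het_error_rate = 0.01,
                                info_shape1 = 8, info_shape2 = 1,
                                female_fraction = 0, seed = 1) {
  founders <- sample_ids(panel)
  if (length(founders) == 0) stop("empty founder panel")
  groups <- attr(panel, "founder_groups")
  if (is.null(founder_frequencies)) {
    founder_frequencies <- stats::setNames(numeric(length(founders)), founders)
    founder_frequencies[match(c("REF_GROUP", "ALT_GROUP"), groups)] <- c(0.633, 0.367)
  }
  if (is.null(names(founder_frequencies))) names(founder_frequencies) <- founders
  if (abs(sum(founder_frequencies) - 1) > 1e-8)
    stop("founder_frequencies must sum to 1")
  if (het_error_rate < 0 || het_error_rate > 1 ||
      missing_rate_mean < 0 || missing_rate_mean > 1)
    stop("rates must be in [0, 1]")
  if (missing_rate_mean + het_error_rate > 1)
    stop("missing_rate_mean + het_error_rate must not exceed 1")

  set.seed(derive_seed(seed, "population"))
  n_sites <- ncol(panel$calls)
  origin <- sample(founders, n_samples, replace = TRUE,
                   prob = founder_frequencies[founders])
  latent <- panel$calls[match(origin, founders), , drop = FALSE]

  # per-sample missingness via moment-matched Beta (degenerate when sd = 0)
  if (missing_rate_sd > 0) {
    m <- missing_rate_mean; v <- missing_rate_sd^2
    k <- m * (1 - m) / v - 1
    if (k <= 0) stop("missing_rate_sd too large for the given mean")
    miss_rate <- stats::rbeta(n_samples, m * k, (1 - m) * k)
  } else {
    miss_rate <- rep(missing_rate_mean, n_samples)
  }

  u <- matrix(stats::runif(n_samples * n_sites), n_samples, n_sites)
  calls <- latent
  calls[u < miss_rate + het_error_rate] <- 1L        # HET band
  calls[u < miss_rate] <- NA_integer_                # MISSING band (overrides)
  rownames(calls) <- paste0("S", seq_len(n_samples))

  variants <- panel$variants
  variants$info_score <- stats::rbeta(n_sites, info_shape1, info_shape2)
  gm <- geno_matrix(calls, variants)

  sex <- rep("male", n_samples)
  if (female_fraction > 0)
    sex[stats::runif(n_samples) < female_fraction] <- "female"
  truth <- data.frame(sample_id = rownames(calls), founder = origin,
                      haplogroup = unname(groups[origin]), sex = sex,
                      missing_rate = miss_rate, stringsAsFactors = FALSE)
  list(matrix = gm, truth = truth)
}

#' Simulate autosomal dosages with optional sibship structure
#'
#' Draws per-SNP allele frequencies uniformly on `maf_range`, then builds
#' genotype dosages in \{0, 1, 2\}. With `sibship_size > 1` samples are
#' grouped into full sibships: each sibship has four parental haplotypes
#' (Bernoulli(p) per SNP) and every sib inherits one maternal and one
#' paternal haplotype chosen independently per SNP, so full sibs have
#' expected genomic relationship ~0.5 while unrelated pairs are ~0.
#'
#' @param n_samples number of samples (divisible by `sibship_size`)
#' @param n_snps number of autosomal SNPs
#' @param sibship_size sibs per family (1 = unrelated)
#' @param maf_range range the allele frequencies are drawn from
#' @param seed integer seed
#' @return list: `dosages` (n x m matrix, rownames `S1..`), `freq` (true
#'   allele frequencies), `sibship` (integer family id per sample)
#' @export
simulate_autosomal_dosages <- function(n_samples, n_snps, sibship_size = 1,
                                       maf_range = c(0.05, 0.95), seed = 1) {
  if (sibship_size > 1 && n_samples %% sibship_size != 0)
    stop("n_samples must be divisible by sibship_size")
  set.seed(derive_seed(seed, "autosomes"))
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  ids <- paste0("S", seq_len(n_samples))
  if (sibship_size == 1) {
    dos <- matrix(stats::rbinom(n_samples * n_snps, 2L, rep(p, each = n_samples)),
                  n_samples, n_snps, dimnames = list(ids, NULL))
    return(list(dosages = dos, freq = p, sibship = seq_len(n_samples)))
  }
  n_fam <- n_samples %/% sibship_size
  dos <- matrix(0L, n_samples, n_snps, dimnames = list(ids, NULL))
  row <- 1L
  for (fam in seq_len(n_fam)) {
    par_hap <- matrix(stats::rbinom(4L * n_snps, 1L, rep(p, each = 4L)), 4L, n_snps)
    for (s in seq_len(sibship_size)) {
      mat_pick <- stats::rbinom(n_snps, 1L, 0.5)        # maternal hap 1 or 2
      pat_pick <- stats::rbinom(n_snps, 1L, 0.5)
      mat <- ifelse(mat_pick == 1L, par_hap[1, ], par_hap[2, ])
      pat <- ifelse(pat_pick == 1L, par_hap[3, ], par_hap[4, ])
      dos[row, ] <- mat + pat
      row <- row + 1L
    }
  }
  list(dosages = dos, freq = p, sibship = rep(seq_len(n_fam), each = sibship_size))
}

#' Assign haplogroups along sibship lines (confounded scenario)
#'
#' Gives every member of a sibship the same haplogroup (as paternal
#' inheritance of Y would), coupling family structure to haplogroup so
#' that naive association tests on polygenic traits are confounded.
#'
#' @param sibship integer family id per sample
#' @param p_alt probability a sibship carries the alternate haplogroup
#' @param seed integer seed
#' @return character vector of REF_GROUP/ALT_GROUP per sample
#' @export
sibship_haplogroups <- function(sibship, p_alt = 0.4, seed = 1) {
  set.seed(derive_seed(seed, "sibship_groups"))
  fams <- unique(sibship)
  grp <- ifelse(stats::runif(length(fams)) < p_alt, "ALT_GROUP", "REF_GROUP")
  names(grp) <- as.character(fams)
  unname(grp[as.character(sibship)])
}

#' Simulate polygenic phenotypes with optional haplotype effects
#'
#' Each trait is `covariate effects + polygenic term + hap_effect x
#' I(alternate haplogroup) + residual`. The polygenic term is built from
#' the standardized autosomal dosages and scaled to variance
#' `heritability`; the residual has variance `1 - heritability`, so
#' `hap_effect` is in within-group standard-deviation units.
#'
#' @param dosages autosomal dosage matrix (samples x SNPs)
#' @param haplogroup character vector REF_GROUP/ALT_GROUP per sample (or
#'   NA; NA samples get no haplotype term)
#' @param n_traits number of traits
#' @param heritability polygenic variance fraction on \[0, 1\]
#' @param hap_effect scalar or per-trait vector of haplotype effects in
#'   sd units (0 = null trait)
#' @param covariate_effects coefficients for simulated standard-normal
#'   covariates (default none)
#' @param seed integer seed
#' @return list: `traits` (n x n_traits matrix), `covariates` (n x k or
#'   NULL), `truth` (data frame trait, hap_effect)
#' @export
simulate_phenotypes <- function(dosages, haplogroup, n_traits = 1,
                                heritability = 0.5, hap_effect = 0,
                                covariate_effects = numeric(0), seed = 1) {
  if (heritability < 0 || heritability > 1) stop("heritability must be in [0, 1]")
  n <- nrow(dosages)
  if (length(haplogroup) != n) stop("haplogroup length must match samples")
  set.seed(derive_seed(seed, "phenotypes"))
  hap_effect <- rep_len(hap_effect, n_traits)

  p <- colMeans(dosages) / 2
  ok <- p > 0 & p < 1
  Z <- sweep(dosages[, ok, drop = FALSE], 2, 2 * p[ok])
  Z <- sweep(Z, 2, sqrt(2 * p[ok] * (1 - p[ok])), "/")
  m <- ncol(Z)

  G <- if (heritability > 0) {
    B <- matrix(stats::rnorm(m * n_traits), m, n_traits)
    Z %*% B * sqrt(heritability / m)
  } else matrix(0, n, n_traits)

  k <- length(covariate_effects)
  C <- NULL
  cov_term <- 0
  if (k > 0) {
    C <- matrix(stats::rnorm(n * k), n, k,
                dimnames = list(rownames(dosages), paste0("cov", seq_len(k))))
    cov_term <- C %*% covariate_effects
  }
  ind <- as.numeric(haplogroup == "ALT_GROUP")
  ind[is.na(ind)] <- 0
  E <- matrix(stats::rnorm(n * n_traits, sd = sqrt(1 - heritability)), n, n_traits)
  traits <- G + E + outer(ind, hap_effect) + as.vector(cov_term)
  dimnames(traits) <- list(rownames(dosages), paste0("trait", seq_len(n_traits)))
  list(traits = traits, covariates = C,
       truth = data.frame(trait = colnames(traits), hap_effect = hap_effect,
                          stringsAsFactors = FALSE))
}

#' Simulate negative-binomial expression counts
#'
#' Gene counts are negative binomial around per-gene baseline means, with
#' library-size variation across samples. Differentially expressed genes
#' have their mean multiplied by a fold change in the alternate
#' haplogroup. Male-specific genes (e.g. Y-linked transcripts) emit zero
#' counts in females.
#'
#' @param haplogroup REF_GROUP/ALT_GROUP per sample
#' @param sex "male"/"female" per sample
#' @param n_genes number of genes
#' @param baseline_log_mean per-gene natural-log mean count (scalar
#'   recycled)
#' @param dispersion per-gene negative-binomial dispersion (>0; scalar
#'   recycled); variance = mu + dispersion * mu^2
#' @param de_genes named numeric vector: names are gene ids (`g<i>`),
#'   values are fold changes applied in the alternate haplogroup
#' @param male_specific_genes character vector of gene ids all-zero in
#'   females
#' @param library_size_range relative library-size factor range
#' @param seed integer seed
#' @return list: `counts` (genes x samples integer matrix), `truth`
#'   (data frame gene, fold_change, de, male_specific)
#' @export
simulate_expression <- function(haplogroup, sex = NULL, n_genes = 200,
                                baseline_log_mean = log(100), dispersion = 0.1,
                                de_genes = numeric(0),
                                male_specific_genes = character(0),
                                library_size_range = c(0.7, 1.3), seed = 1) {
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  n <- length(haplogroup)
  if (is.null(sex)) sex <- rep("male", n)
  set.seed(derive_seed(seed, "expression"))
  genes <- paste0("g", seq_len(n_genes))
  if (length(de_genes) && !all(names(de_genes) %in% genes))
    stop("de_genes names must be gene ids present in the matrix")
  mu0 <- exp(rep_len(baseline_log_mean, n_genes))
  disp <- rep_len(dispersion, n_genes)
  fc <- stats::setNames(rep(1, n_genes), genes)
  fc[names(de_genes)] <- de_genes

  lib <- stats::runif(n, library_size_range[1], library_size_range[2])
  alt <- !is.na(haplogroup) & haplogroup == "ALT_GROUP"
  mu <- outer(mu0, lib)                       # genes x samples
  mu[, alt] <- mu[, alt] * fc                 # fold change in ALT group
  counts <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = rep(1 / disp, n)),
                   n_genes, n, dimnames = list(genes, paste0("S", seq_len(n))))
  if (length(male_specific_genes))
    counts[male_specific_genes, sex == "female"] <- 0L
  truth <- data.frame(gene = genes, fold_change = unname(fc),
                      de = unname(fc != 1),
                      male_specific = genes %in% male_specific_genes,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}
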