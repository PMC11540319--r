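#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test on genotype counts: conditional on the observed
#' allele counts, heterozygote counts with the same parity are enumerated
#' and the p-value is the summed probability of all outcomes no more
#' likely than the observed one (Wigginton-style conditional
#' enumeration). Exact enumeration stays valid at extreme thresholds
#' (e.g. 1e-10) where the chi-square approximation is unreliable.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts
#' @return the exact two-sided p-value
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2 * n_aa + n_Aa
  n_r <- min(n_a, 2 * n - n_a)  # rarer allele count
  if (n_r == 0) return(1)       # monomorphic: single possible outcome
  hets <- seq(n_r %% 2, n_r, by = 2)
  # log P(het = h | n, n_r) up to a common constant
  logp <- vapply(hets, function(h) {
    hom_r <- (n_r - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Filter autosomal dosages for GRM construction
#'
#' Removes SNPs with a missing rate strictly above `max_missing`,
#' violating Hardy-Weinberg equilibrium at `hwe_p_min` (exact test,
#' optionally on a sex subset, as when only females are diploid for X),
#' or with minor allele frequency below `maf_min`.
#'
#' @param dosages samples x SNPs matrix of dosages in \{0, 1, 2, NA\}
#' @param max_missing per-SNP missing-rate ceiling (strict >) (default 0.1)
#' @param hwe_p_min minimum HWE exact p (default 1e-10)
#' @param maf_min minimum minor allele frequency (default 0.005)
#' @param hwe_subset optional logical/index vector of samples used for
#'   the HWE test (e.g. females only); all samples by default
#' @return list: `dosages` (filtered), `report` (per-criterion removals)
#' @export
grm_snp_filters <- function(dosages, max_missing = 0.1, hwe_p_min = 1e-10,
                            maf_min = 0.005, hwe_subset = NULL) {
  miss <- colMeans(is.na(dosages))
  keep <- miss <= max_missing
  n_miss <- sum(!keep)

  hwe_mat <- if (is.null(hwe_subset)) dosages else dosages[hwe_subset, , drop = FALSE]
  hwe_p <- rep(1, ncol(dosages))
  for (j in which(keep)) {
    g <- hwe_mat[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) next
    hwe_p[j] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  drop_hwe <- keep & hwe_p < hwe_p_min
  keep <- keep & !drop_hwe

  freq <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  drop_maf <- keep & (is.na(maf) | maf < maf_min)
  keep <- keep & !drop_maf

  if (!any(keep)) stop("all SNPs removed by GRM filters")
  list(dosages = dosages[, keep, drop = FALSE],
       report = data.frame(criterion = c("missingness", "hwe", "maf"),
                           removed = c(n_miss, sum(drop_hwe), sum(drop_maf)),
                           threshold = c(max_missing, hwe_p_min, maf_min)))
}

#' Genetic relationship matrix from autosomal dosages
#'
#' `A[j,k]` is the average over SNPs of
#' `(x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`, with allele
#' frequencies `p_i` estimated from the sample and the average taken over
#' SNPs non-missing in both members of the pair.
#'
#' @param dosages filtered samples x SNPs dosage matrix
#' @return list of class `grm`: `A` (n x n symmetric matrix), `n_snps`
#'   (per-pair SNP counts used)
#' @export
compute_grm <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP reached compute_grm; apply grm_snp_filters first")
  Z <- sweep(dosages, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- (!is.na(Z)) * 1
  Z[is.na(Z)] <- 0
  M <- tcrossprod(obs)
  if (any(M == 0)) stop("a sample pair shares no genotyped SNP")
  A <- tcrossprod(Z) / M
  dimnames(A) <- dimnames(M) <- list(rownames(dosages), rownames(dosages))
  structure(list(A = A, n_snps = M), class = "grm")
}
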