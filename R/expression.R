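#' Filter genes by detection rate
#'
#' A gene is retained iff it shows detectable expression (count above
#' `detect_threshold`, default "any read") in at least `min_fraction` of
#' samples; genes detected in strictly less than that fraction are
#' excluded.
#'
#' @param counts genes x samples count matrix
#' @param min_fraction minimum fraction of samples with detectable
#'   expression (default 0.10)
#' @param detect_threshold a count strictly above this is "detectable"
#'   (default 0)
#' @return the retained count matrix
#' @export
filter_genes <- function(counts, min_fraction = 0.10, detect_threshold = 0) {
  frac <- rowMeans(counts > detect_threshold)
  counts[frac >= min_fraction, , drop = FALSE]
}

#' TMM normalization factors and counts per million
#'
#' Trimmed mean of M-values between-sample normalization: a reference
#' sample is chosen as the one whose upper-quartile count fraction is
#' closest to the mean of those fractions; each sample's factor is the
#' precision-weighted mean of its log2 count ratios against the
#' reference after trimming 30% of M-values (log ratios) and 5% of
#' A-values (log abundances); factors are rescaled to geometric mean 1.
#' Normalized expression is `count / (library size x factor) x 1e6`.
#'
#' @param counts genes x samples matrix of raw counts
#' @return list: `factors` (per-sample, geometric mean 1), `ref_sample`
#'   (column name or index of the reference), `cpm` (TMM-scaled
#'   counts-per-million matrix), `lib_size`
#' @export
tmm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  cpm <- sweep(counts, 2, lib * f, "/") * 1e6
  list(factors = f,
       ref_sample = if (!is.null(colnames(counts))) colnames(counts)[ref] else ref,
       cpm = cpm, lib_size = lib)
}

#' Mann-Whitney (Wilcoxon rank-sum) two-sample test
#'
#' U statistic from summed ranks with average ranks for ties. The exact
#' null distribution is used when both groups have at most 25
#' observations and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. Two-sided.
#'
#' @param a,b numeric vectors (both nonempty)
#' @return list: `U`, `p`, `exact` (whether the exact distribution was
#'   used)
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 25 && length(b) <= 25 && !ties
  wt <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Differential expression scan by haplogroup
#'
#' For each tissue: samples with a haplogroup assignment are retained,
#' genes detected in fewer than `min_fraction` of the retained samples
#' are excluded, counts are TMM-normalized to CPM, and each gene is
#' tested REF_GROUP vs ALT_GROUP with a Mann-Whitney test. BH q-values
#' are computed across all genes in all tissues for the chromosome type
#' (per-tissue pooling optional). A tissue where only one haplogroup is
#' present is skipped with a warning.
#'
#' @param counts a genes x samples count matrix, or a named list of such
#'   matrices (one per tissue)
#' @param assignments output of [assign_haplogroups()] for the
#'   chromosome type
#' @param chrom_type `"Y"` or `"MT"` (label carried into the results)
#' @param tissue tissue label when `counts` is a single matrix
#' @param min_fraction gene detection threshold (default 0.10)
#' @param pooling `"all"` (BH across genes x tissues, the default) or
#'   `"per_tissue"`
#' @return data frame: gene, tissue, chrom_type, n_ref, n_alt,
#'   median_ref, median_alt, U, p, q
#' @export
de_scan <- function(counts, assignments, chrom_type = "Y", tissue = "tissue1",
                    min_fraction = 0.10, pooling = c("all", "per_tissue")) {
  pooling <- match.arg(pooling)
  if (!is.list(counts)) counts <- stats::setNames(list(counts), tissue)
  res <- list()
  for (tis in names(counts)) {
    cm <- as.matrix(counts[[tis]])
    lab <- assignments$label[match(colnames(cm), assignments$sample_id)]
    keep <- !is.na(lab) & lab %in% c("REF_GROUP", "ALT_GROUP")
    cm <- cm[, keep, drop = FALSE]
    lab <- lab[keep]
    if (length(unique(lab)) < 2) {
      warning("tissue '", tis, "' has a single haplogroup; skipped")
      next
    }
    cm <- filter_genes(cm, min_fraction = min_fraction)
    if (nrow(cm) == 0) next
    norm <- tmm_normalize(cm)
    is_ref <- lab == "REF_GROUP"
    rows <- lapply(rownames(cm), function(g) {
      va <- norm$cpm[g, is_ref]; vb <- norm$cpm[g, !is_ref]
      mw <- mann_whitney(va, vb)
      data.frame(gene = g, tissue = tis, chrom_type = chrom_type,
                 n_ref = length(va), n_alt = length(vb),
                 median_ref = stats::median(va), median_alt = stats::median(vb),
                 U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    })
    res[[tis]] <- do.call(rbind, rows)
  }
  if (length(res) == 0)
    return(data.frame(gene = character(0), tissue = character(0),
                      chrom_type = character(0), n_ref = integer(0),
                      n_alt = integer(0), median_ref = numeric(0),
                      median_alt = numeric(0), U = numeric(0),
                      p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (pooling == "all") {
    out$q <- bh_fdr(out$p)
  } else {
    out$q <- NA_real_
    for (tis in unique(out$tissue)) {
      i <- out$tissue == tis
      out$q[i] <- bh_fdr(out$p[i])
    }
  }
  out
}

#' Sex-stratified X-SNP linear scan against expression
#'
#' Per sex stratum and per SNP with at least `min_carriers` carriers of
#' the minor allele (within the stratum), fits an ordinary linear model
#' of expression on the 0/1/2 SNP dosage; in males the Y haplogroup
#' indicator is included as a covariate. Strata with fewer than 3
#' samples are skipped.
#'
#' @param expr numeric expression vector (one gene), named or aligned
#'   with rows of `geno`
#' @param geno samples x SNPs dosage matrix in \{0, 1, 2, NA\} (already
#'   filtered as for the GRM, with HWE on females only)
#' @param sex "male"/"female" per sample
#' @param y_assignments optional [assign_haplogroups()] table providing
#'   the male Y-haplogroup covariate
#' @param min_carriers minimum minor-allele carriers for a reported p
#'   (default 5)
#' @return data frame: snp, stratum, n, n_carriers, slope, p
#' @export
xsnp_linear_scan <- function(expr, geno, sex, y_assignments = NULL,
                             min_carriers = 5) {
  geno <- as.matrix(geno)
  snps <- colnames(geno) %||% paste0("snp", seq_len(ncol(geno)))
  hap <- rep(NA_real_, length(expr))
  if (!is.null(y_assignments)) {
    enc <- encode_haplotype(y_assignments)
    hap <- unname(enc[match(rownames(geno), names(enc))])
  }
  out <- list()
  for (stratum in c("female", "male")) {
    idx <- which(sex == stratum & !is.na(expr))
    if (length(idx) < 3) next
    for (j in seq_len(ncol(geno))) {
      g <- geno[idx, j]
      ok <- !is.na(g)
      covar <- NULL
      if (stratum == "male") {
        ok <- ok & !is.na(hap[idx])
        covar <- hap[idx]
      }
      g_ok <- g[ok]; y_ok <- expr[idx][ok]
      if (length(g_ok) < 3) next
      freq <- mean(g_ok) / 2
      n_carriers <- if (freq <= 0.5) sum(g_ok >= 1) else sum(g_ok <= 1)
      if (n_carriers < min_carriers) next
      X <- if (stratum == "male") cbind(1, g_ok, covar[ok]) else cbind(1, g_ok)
      if (qr(X)$rank < ncol(X)) next
      fit <- stats::lm.fit(X, y_ok)
      dfree <- length(y_ok) - ncol(X)
      if (dfree < 1) next
      s2 <- sum(fit$residuals^2) / dfree
      XtXinv <- chol2inv(chol(crossprod(X)))
      se <- sqrt(s2 * XtXinv[2, 2])
      slope <- unname(fit$coefficients[2])
      tval <- slope / se
      out[[length(out) + 1]] <- data.frame(
        snp = snps[j], stratum = stratum, n = length(y_ok),
        n_carriers = n_carriers, slope = slope,
        p = 2 * stats::pt(abs(tval), dfree, lower.tail = FALSE),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (length(out) == 0)
    return(data.frame(snp = character(0), stratum = character(0),
                      n = integer(0), n_carriers = integer(0),
                      slope = numeric(0), p = numeric(0)))
  do.call(rbind, out)
}
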