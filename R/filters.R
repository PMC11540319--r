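#' Genotype filter configuration
#'
#' The filter cascade removes, always in this order: (1) variants with a
#' low imputation INFO score, (2) variants with a minor allele frequency
#' of zero, (3) variants with a high missing rate (strictly greater than
#' `max_snp_missing`), and (4) samples with a high missing rate (strictly
#' greater than `max_sample_missing`). Individual stages can be disabled
#' per analysis, but the order of the enabled stages is fixed.
#'
#' @param info_min minimum INFO score; variants with `info_score <
#'   info_min` are removed. Variants with no INFO score are retained at
#'   this stage. Default 0.9.
#' @param drop_maf_zero remove variants whose minor allele frequency is 0
#'   (monomorphic among non-missing calls). Default TRUE.
#' @param max_snp_missing per-variant missing-rate ceiling; rates exactly
#'   at the threshold are retained. Default 0.25.
#' @param max_sample_missing per-sample missing-rate ceiling (strict).
#'   Default 0.50.
#' @param stages ordered subset of `c("INFO","MAF","SNP_MISSING","SAMPLE_MISSING")`
#'   to run. The canonical order is enforced regardless of the order given.
#' @return a `filter_config` list
#' @export
filter_config <- function(info_min = 0.9, drop_maf_zero = TRUE,
                          max_snp_missing = 0.25, max_sample_missing = 0.50,
                          stages = c("INFO", "MAF", "SNP_MISSING", "SAMPLE_MISSING")) {
  all_stages <- c("INFO", "MAF", "SNP_MISSING", "SAMPLE_MISSING")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown filter stage(s): ", paste(bad, collapse = ", "))
  for (x in c(info_min, max_snp_missing, max_sample_missing))
    if (!is.numeric(x) || x < 0 || x > 1) stop("filter thresholds must be in [0, 1]")
  structure(list(info_min = info_min, drop_maf_zero = isTRUE(drop_maf_zero),
                 max_snp_missing = max_snp_missing,
                 max_sample_missing = max_sample_missing,
                 stages = all_stages[all_stages %in% stages]),
            class = "filter_config")
}

# haploid-style allele counts per variant: a surviving HET (non-hemizygous
# chromosome) contributes one REF and one ALT allele; MISSING contributes none
.allele_counts <- function(calls) {
  n_ref <- colSums(calls == 0L, na.rm = TRUE) + colSums(calls == 1L, na.rm = TRUE)
  n_alt <- colSums(calls == 2L, na.rm = TRUE) + colSums(calls == 1L, na.rm = TRUE)
  cbind(n_ref = n_ref, n_alt = n_alt)
}

#' Apply the ordered genotype filter cascade
#'
#' Stages run in the fixed order INFO -> MAF -> SNP_MISSING ->
#' SAMPLE_MISSING, skipping disabled ones; each stage is computed on the
#' matrix as left by the previous stage (per-variant missing rates over
#' the current samples, per-sample rates over the current variants).
#' A variant with all calls missing has undefined MAF and is removed at
#' the MAF stage when that stage is enabled, otherwise at SNP_MISSING.
#'
#' @param gm a [geno_matrix()]
#' @param config a [filter_config()]
#' @return list with `matrix` (filtered [geno_matrix()]) and `report`
#'   (data frame: stage, enabled, examined, removed, threshold), plus
#'   `dims_in`/`dims_out`.
#' @export
apply_filter_cascade <- function(gm, config = filter_config()) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(config, "filter_config"))
  if (nrow(gm$calls) == 0 || ncol(gm$calls) == 0) stop("empty genotype matrix")
  dims_in <- dim(gm$calls)
  all_stages <- c("INFO", "MAF", "SNP_MISSING", "SAMPLE_MISSING")
  rep <- data.frame(stage = all_stages, enabled = all_stages %in% config$stages,
                    examined = NA_integer_, removed = NA_integer_,
                    threshold = NA_real_, stringsAsFactors = FALSE)

  fail_if_empty <- function(stage) {
    if (nrow(gm$calls) == 0 || ncol(gm$calls) == 0)
      stop("filter stage ", stage, " removed all remaining ",
           if (stage == "SAMPLE_MISSING") "samples" else "variants")
  }
  mark <- function(stage, examined, removed, threshold) {
    i <- match(stage, rep$stage)
    rep$examined[i] <<- examined; rep$removed[i] <<- removed
    rep$threshold[i] <<- threshold
  }

  if ("INFO" %in% config$stages) {
    info <- gm$variants$info_score
    drop <- !is.na(info) & info < config$info_min
    mark("INFO", length(drop), sum(drop), config$info_min)
    gm <- gm_subset(gm, variants = !drop)
    fail_if_empty("INFO")
  }
  if ("MAF" %in% config$stages && config$drop_maf_zero) {
    ac <- .allele_counts(gm$calls)
    tot <- ac[, 1] + ac[, 2]
    maf <- ifelse(tot > 0, pmin(ac[, 1], ac[, 2]) / tot, NA_real_)
    drop <- is.na(maf) | maf == 0  # all-missing variants removed here
    mark("MAF", length(drop), sum(drop), 0)
    gm <- gm_subset(gm, variants = !drop)
    fail_if_empty("MAF")
  }
  if ("SNP_MISSING" %in% config$stages) {
    rate <- colMeans(is.na(gm$calls))
    drop <- rate > config$max_snp_missing
    mark("SNP_MISSING", length(drop), sum(drop), config$max_snp_missing)
    gm <- gm_subset(gm, variants = !drop)
    fail_if_empty("SNP_MISSING")
  }
  if ("SAMPLE_MISSING" %in% config$stages) {
    rate <- rowMeans(is.na(gm$calls))
    drop <- rate > config$max_sample_missing
    mark("SAMPLE_MISSING", length(drop), sum(drop), config$max_sample_missing)
    gm <- gm_subset(gm, samples = !drop)
    fail_if_empty("SAMPLE_MISSING")
  }
  list(matrix = gm, report = rep, dims_in = dims_in, dims_out = dim(gm$calls))
}

#' Write a filter report as TSV
#' @param result return value of [apply_filter_cascade()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_filter_report <- function(result, path) {
  utils::write.table(result$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
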