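#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a (possibly gzipped) VCF v4.2 file into a [geno_matrix()].
#' Only biallelic SNPs on the requested chromosome are retained;
#' multiallelic records and indels are dropped (with a message giving the
#' count). Diploid genotypes map `0/0 -> REF`, `0/1`/`1/0` (and phased
#' equivalents) `-> HET`, `1/1 -> ALT`, `./.` `-> MISSING`; haploid
#' genotypes map `0 -> REF`, `1 -> ALT`, `. -> MISSING`. Imputation
#' quality is read from the INFO field named by `info_key` when present.
#'
#' @param path path to a VCF file (plain or gzipped)
#' @param chromosome chromosome label to extract (required; errors if absent)
#' @param info_key INFO field carrying the per-variant imputation quality
#'   score on \[0, 1\]. Default `"INFO_SCORE"`.
#' @return a [geno_matrix()]
#' @export
read_vcf <- function(path, chromosome, info_key = "INFO_SCORE") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chroms <- fix[, "CHROM"]
  if (!chromosome %in% chroms)
    stop("chromosome '", chromosome, "' not present in ", path)
  keep_chr <- chroms == chromosome
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  n_drop <- sum(keep_chr & !is_snp)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop, " non-biallelic-SNP record(s)")
  keep <- keep_chr & is_snp
  if (!any(keep))
    stop("no biallelic SNPs on chromosome '", chromosome, "' in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # strip phasing, then map genotype strings to call codes
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt == "0/0" | gt == "0"] <- 0L
  code[gt == "0/1" | gt == "1/0"] <- 1L
  code[gt == "1/1" | gt == "1"] <- 2L

  info <- vcfR::extract.info(v, element = info_key, as.numeric = TRUE)[keep]
  variants <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    info_score = as.numeric(info),
    stringsAsFactors = FALSE
  )
  calls <- t(code)
  rownames(calls) <- colnames(gt)
  geno_matrix(calls, variants)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Serializes a [geno_matrix()] to plain-text VCF with 1-based positions,
#' a `GT` FORMAT field and the INFO score under `info_key`. Hemizygous
#' conventions are preserved: calls are written as diploid genotypes
#' (`0/0`, `0/1`, `1/1`, `./.`) so the file round-trips through
#' [read_vcf()].
#'
#' @param gm a [geno_matrix()]
#' @param path output path
#' @param info_key INFO field name used for the per-variant score
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path, info_key = "INFO_SCORE") {
  v <- gm$variants
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(gm$calls), ncol = nrow(gm$calls))
  ok <- !is.na(t(gm$calls))
  gt[ok] <- gtmap[t(gm$calls)[ok] + 1L]
  info <- ifelse(is.na(v$info_score), ".",
                 paste0(info_key, "=", formatC(v$info_score, format = "g", digits = 6)))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation quality score\">", info_key),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            sample_ids(gm)), collapse = "\t")
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Mask heterozygous calls on a hemizygous chromosome
#'
#' Y and MT are hemizygous, so heterozygous genotype calls are biologically
#' impossible and indicate error; every HET call is converted to MISSING.
#' The caller asserts that `gm` is from a hemizygous chromosome.
#'
#' @param gm a [geno_matrix()]
#' @return list with `matrix` (the masked [geno_matrix()]) and
#'   `masked_count` (number of HET calls converted)
#' @export
mask_hemizygous_hets <- function(gm) {
  het <- !is.na(gm$calls) & gm$calls == 1L
  gm$calls[het] <- NA_integer_
  list(matrix = gm, masked_count = sum(het))
}

#' Read sample metadata
#'
#' Tab-separated table with columns `sample_id`, `sex` (male/female/unknown)
#' and optional `birth_date`, `library_prep`.
#'
#' @param path TSV path
#' @return data frame, one row per sample
#' @export
read_sample_meta <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sex") %in% names(m)))
    stop("sample metadata needs columns sample_id, sex")
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(m$sex), c("male", "female", "unknown"))
  if (length(bad)) stop("invalid sex values: ", paste(bad, collapse = ", "))
  m
}
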