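#' Genotype matrix container
#'
#' A `geno_matrix` holds biallelic SNP calls for a set of samples on one
#' chromosome. Calls are stored as an integer matrix (samples x variants)
#' with the encoding `0 = REF`, `1 = HET`, `2 = ALT`, `NA = MISSING`.
#' Variant metadata (chromosome, 1-based position, alleles, optional
#' imputation INFO score) travels alongside in a data frame.
#'
#' @param calls integer matrix, samples in rows and variants in columns.
#'   Row names are sample ids. Values must be in \{0, 1, 2, NA\}.
#' @param variants data frame with one row per variant and columns
#'   `chrom`, `pos` (1-based), `ref`, `alt`, and optionally `info_score`
#'   (in \[0, 1\] or NA).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, variants) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) stop("`calls` must have sample ids as row names")
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
    stop("calls must be 0 (REF), 1 (HET), 2 (ALT) or NA (MISSING)")
  if (!is.data.frame(variants)) stop("`variants` must be a data frame")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("`variants` needs columns: ", paste(need, collapse = ", "))
  if (nrow(variants) != ncol(calls))
    stop("variant table rows (", nrow(variants), ") != call columns (", ncol(calls), ")")
  if (is.null(variants$info_score)) variants$info_score <- NA_real_
  # variants must be position-sorted within chromosome
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  structure(list(calls = calls, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmis <- mean(is.na(x$calls))
  cat(sprintf("geno_matrix: %d samples x %d variants (%s), %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              paste(unique(x$variants$chrom), collapse = ","), 100 * nmis))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Sample ids of a genotype matrix
#' @param gm a `geno_matrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(gm) rownames(gm$calls)

#' Subset a genotype matrix
#'
#' @param gm a `geno_matrix`
#' @param samples sample ids or logical/integer index over rows
#' @param variants logical/integer index over variant columns
#' @return the subsetted `geno_matrix`
#' @export
gm_subset <- function(gm, samples = NULL, variants = NULL) {
  calls <- gm$calls
  vtab <- gm$variants
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  if (!is.null(variants)) {
    calls <- calls[, variants, drop = FALSE]
    vtab <- vtab[variants, , drop = FALSE]
    rownames(vtab) <- NULL
  }
  structure(list(calls = calls, variants = vtab), class = "geno_matrix")
}

# internal: variant keys used to intersect two matrices/panels
variant_key <- function(variants) paste(variants$chrom, variants$pos, sep = ":")
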