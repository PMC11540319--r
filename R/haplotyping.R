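#' Per-sample allele counts
#'
#' Counts reference, alternate and missing calls per sample. On a
#' hemizygous-masked matrix every variant falls in exactly one bucket, so
#' `n_ref + n_alt + n_missing` equals the variant count.
#'
#' @param gm a hemizygous-masked [geno_matrix()] (no HET calls)
#' @return data frame: sample_id, n_ref, n_alt, n_missing
#' @export
count_alleles <- function(gm) {
  if (any(gm$calls == 1L, na.rm = TRUE))
    stop("HET calls present; run mask_hemizygous_hets() first")
  data.frame(
    sample_id = sample_ids(gm),
    n_ref = as.integer(rowSums(gm$calls == 0L, na.rm = TRUE)),
    n_alt = as.integer(rowSums(gm$calls == 2L, na.rm = TRUE)),
    n_missing = as.integer(rowSums(is.na(gm$calls))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Assign samples to haplogroups by majority allele
#'
#' A sample with more reference than alternate alleles goes to
#' `REF_GROUP`, more alternate to `ALT_GROUP`; an exact tie gives
#' `UNASSIGNED` (never broken arbitrarily). Downstream association and
#' consensus code exclude UNASSIGNED samples.
#'
#' @param counts output of [count_alleles()]
#' @return data frame: sample_id, label, n_ref, n_alt, n_missing
#' @export
assign_haplogroups <- function(counts) {
  label <- ifelse(counts$n_ref > counts$n_alt, "REF_GROUP",
                  ifelse(counts$n_alt > counts$n_ref, "ALT_GROUP", "UNASSIGNED"))
  cbind(data.frame(sample_id = counts$sample_id, label = label,
                   stringsAsFactors = FALSE),
        counts[, c("n_ref", "n_alt", "n_missing")])
}

#' Consensus genotypes for a haplogroup
#'
#' Per variant, the modal non-missing call among the group's members;
#' MISSING when the column has no calls or an exact REF/ALT tie.
#'
#' @param gm a hemizygous-masked [geno_matrix()]
#' @param assignments output of [assign_haplogroups()]
#' @param group `"REF_GROUP"` or `"ALT_GROUP"`
#' @return integer vector (length = variant count) with values 0, 2 or NA,
#'   carrying the variant table as attribute `"variants"` and the group as
#'   attribute `"group"`.
#' @export
consensus_genotypes <- function(gm, assignments, group) {
  ids <- assignments$sample_id[assignments$label == group]
  if (length(ids) == 0) stop("no samples assigned to group ", group)
  sub <- gm$calls[match(ids, sample_ids(gm)), , drop = FALSE]
  nref <- colSums(sub == 0L, na.rm = TRUE)
  nalt <- colSums(sub == 2L, na.rm = TRUE)
  cons <- ifelse(nref > nalt, 0L, ifelse(nalt > nref, 2L, NA_integer_))
  cons <- as.integer(cons)
  attr(cons, "variants") <- gm$variants
  attr(cons, "group") <- group
  cons
}

#' Hamming divergence between two consensus haplotypes
#'
#' Counts differing sites over sites called (non-missing) in both.
#'
#' @param cons_a,cons_b consensus vectors from [consensus_genotypes()]
#' @return list: `n_diff`, `n_comparable`
#' @export
consensus_divergence <- function(cons_a, cons_b) {
  ok <- !is.na(cons_a) & !is.na(cons_b)
  list(n_diff = sum(cons_a[ok] != cons_b[ok]), n_comparable = sum(ok))
}

#' Match a consensus haplotype to founder strains
#'
#' Hamming distance of the consensus to each founder haplotype over the
#' shared variant set (matched by chromosome and position), ignoring sites
#' missing in either. The best founder(s) are reported; ties are flagged,
#' never silently broken. A founder with zero comparable sites is marked
#' incomparable (NA distance).
#'
#' @param consensus vector from [consensus_genotypes()]
#' @param panel a [geno_matrix()] whose samples are founder strains
#' @return list: `group`, `distances` (data frame founder, n_diff,
#'   n_comparable, distance), `best` (character vector), `tie` (logical)
#' @export
match_founders <- function(consensus, panel) {
  vtab <- attr(consensus, "variants")
  key_c <- variant_key(vtab)
  key_p <- variant_key(panel$variants)
  shared <- intersect(key_c, key_p)
  if (length(shared) == 0) stop("consensus and founder panel share no variants")
  cvec <- consensus[match(shared, key_c)]
  pmat <- panel$calls[, match(shared, key_p), drop = FALSE]

  founders <- sample_ids(panel)
  res <- data.frame(founder = founders, n_diff = NA_integer_,
                    n_comparable = NA_integer_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(founders)) {
    f <- pmat[i, ]
    ok <- !is.na(cvec) & !is.na(f)
    res$n_comparable[i] <- sum(ok)
    if (sum(ok) > 0) {
      res$n_diff[i] <- sum(cvec[ok] != f[ok])
      res$distance[i] <- res$n_diff[i] / res$n_comparable[i]
    }
  }
  dmin <- suppressWarnings(min(res$distance, na.rm = TRUE))
  if (!is.finite(dmin)) stop("no founder comparable with the consensus")
  best <- res$founder[!is.na(res$distance) & res$distance == dmin]
  list(group = attr(consensus, "group"), distances = res,
       best = best, tie = length(best) > 1)
}

#' Intragroup variation relative to the group consensus
#'
#' Per-sample count of mismatches against the sample's own-group
#' consensus, counted only at sites non-missing in both the sample and
#' the consensus.
#'
#' @param gm a hemizygous-masked [geno_matrix()]
#' @param assignments output of [assign_haplogroups()]
#' @param consensus consensus vector for `group`
#' @param group the group label the consensus belongs to
#' @return list: `per_sample` (data frame sample_id, n_mismatch,
#'   n_comparable), `histogram` (table of mismatch counts)
#' @export
intragroup_variation <- function(gm, assignments, consensus, group) {
  ids <- assignments$sample_id[assignments$label == group]
  sub <- gm$calls[match(ids, sample_ids(gm)), , drop = FALSE]
  cons <- matrix(consensus, nrow = nrow(sub), ncol = length(consensus), byrow = TRUE)
  ok <- !is.na(sub) & !is.na(cons)
  mm <- rowSums(ok & sub != cons)
  per_sample <- data.frame(sample_id = ids, n_mismatch = as.integer(mm),
                           n_comparable = as.integer(rowSums(ok)),
                           stringsAsFactors = FALSE)
  list(per_sample = per_sample, histogram = table(per_sample$n_mismatch))
}

#' Write haplogroup assignments as TSV
#' @param assignments output of [assign_haplogroups()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
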