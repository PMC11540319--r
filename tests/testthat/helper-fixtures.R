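# Build a geno_matrix from compact call strings: "R" = REF, "H" = HET,
# "A" = ALT, "." = MISSING. One string per sample.
gm_from_strings <- function(strings, info_score = NULL, chrom = "Y") {
  codes <- c(R = 0L, H = 1L, A = 2L)
  rows <- lapply(strings, function(s) {
    ch <- strsplit(s, "")[[1]]
    out <- unname(codes[ch])
    out[ch == "."] <- NA_integer_
    out
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- names(strings) %||% paste0("S", seq_along(strings))
  variants <- data.frame(chrom = chrom, pos = seq_len(ncol(calls)),
                         ref = "A", alt = "G",
                         info_score = info_score %||% NA_real_,
                         stringsAsFactors = FALSE)
  geno_matrix(calls, variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal VCF text fixture written to a temp file; returns the path.
write_vcf_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile(fileext = ".vcf", tmpdir = dir)
  writeLines(lines, path)
  path
}

# A random additive distance matrix from a random unrooted tree with
# strictly positive branch lengths; returns both.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_taxa, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}
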