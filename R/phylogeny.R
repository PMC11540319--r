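#' Pairwise Hamming distance matrix, ignoring missingness
#'
#' For each pair of samples, distance = mismatches / comparable sites,
#' where comparable sites are those non-missing in both samples. The
#' per-pair comparable-site counts are returned alongside. A pair with no
#' comparable site is an error (the distance would be undefined).
#'
#' @param gm a [geno_matrix()] with at least two samples
#' @return list of class `hamming_dist`: `d` (symmetric matrix on
#'   \[0, 1\]), `n_comparable` (matrix of per-pair site counts)
#' @export
hamming_distance_matrix <- function(gm) {
  x <- gm$calls
  if (nrow(x) < 2) stop("need at least 2 samples")
  # indicator cross-products: agreements per call state, and per-pair
  # counts of doubly non-missing sites
  obs <- (!is.na(x)) * 1
  comp <- tcrossprod(obs)
  agree <- matrix(0, nrow(x), nrow(x))
  for (s in c(0L, 1L, 2L)) {
    ind <- (!is.na(x) & x == s) * 1
    agree <- agree + tcrossprod(ind)
  }
  if (any(comp[upper.tri(comp)] == 0)) {
    idx <- which(comp == 0 & upper.tri(comp), arr.ind = TRUE)[1, ]
    stop("samples '", rownames(x)[idx[1]], "' and '", rownames(x)[idx[2]],
         "' share no comparable (doubly non-missing) site")
  }
  d <- (comp - agree) / comp
  diag(d) <- 0
  dimnames(d) <- dimnames(comp) <- list(rownames(x), rownames(x))
  structure(list(d = d, n_comparable = comp), class = "hamming_dist")
}

#' Unrooted neighbor-joining tree
#'
#' Standard neighbor joining (Saitou & Nei agglomeration with the
#' Q-criterion) on a symmetric distance matrix. Negative branch lengths
#' can arise on non-additive inputs; by default they are kept as computed
#' and their count flagged in attribute `"n_negative_edges"`. With
#' `clamp_negative = TRUE` each negative edge is set to zero and its
#' length transferred to the adjacent (sister) edge so pairwise path
#' lengths through the parent node are preserved.
#'
#' @param d a `hamming_dist` object, a symmetric numeric matrix with
#'   labels, or a [stats::dist] object; at least 3 taxa
#' @param clamp_negative clamp negative branch lengths to zero
#'   (default FALSE)
#' @return an [ape::nj()] `phylo` tree
#' @export
neighbor_joining <- function(d, clamp_negative = FALSE) {
  if (inherits(d, "hamming_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (nrow(d) < 3) stop("need at least 3 taxa for neighbor joining")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  attr(tr, "n_negative_edges") <- sum(neg)
  if (clamp_negative && any(neg)) {
    for (i in which(tr$edge.length < 0)) {
      parent <- tr$edge[i, 1]
      sibs <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != i)
      if (length(sibs)) {
        tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[i]
      }
      tr$edge.length[i] <- 0
    }
  }
  tr
}

#' Serialize a tree as Newick text
#'
#' @param tree a `phylo` tree with >= 2 leaves
#' @param path optional file to write; when NULL the string is returned
#' @return the Newick string, invisibly when written to file
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (length(tree$tip.label) < 2) stop("tree has fewer than 2 leaves")
  s <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Write a distance matrix as TSV
#' @param d a `hamming_dist` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.data.frame(d$d)
  utils::write.table(cbind(sample_id = rownames(d$d), m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
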