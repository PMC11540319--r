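# Independent brute-force / closed-form oracles used to validate the
# package's statistical kernels. These deliberately take different
# computational routes from the implementation.

# Exact HWE p by a direct counting argument: deal the 2n alleles into n
# individuals; P(h hets | allele counts) = C(n, hom_rare) * C(n - hom_rare, h)
# * 2^h / C(2n, n_rare), summed over outcomes no more probable than observed.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_r <- min(n_a, 2 * n - n_a)
  if (n_r == 0) return(1)
  hets <- seq(n_r %% 2, n_r, by = 2)
  prob <- vapply(hets, function(h) {
    hom_r <- (n_r - h) / 2
    choose(n, hom_r) * choose(n - hom_r, h) * 2^h
  }, numeric(1))
  prob <- prob / choose(2 * n, n_r)
  p_obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# One-sided Fisher p by enumerating which row-1 items land in column 1
# (all C(n, c1) column assignments equally likely under the null).
oracle_fisher_greater <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  items <- c(rep(1, r1), rep(2, r2))
  hits <- 0; total <- 0
  for (idx in utils::combn(n, c1, simplify = FALSE)) {
    total <- total + 1
    if (sum(items[idx] == 1) >= tab[1, 1]) hits <- hits + 1
  }
  hits / total
}

# Two-sided exact Mann-Whitney p by enumerating all group labelings.
oracle_mw_twosided <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a); n <- length(vals)
  r <- rank(vals)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  us <- vapply(utils::combn(n, n1, simplify = FALSE), u_of, numeric(1))
  u_obs <- u_of(seq_len(n1))
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# BH step-up by the textbook loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# TMM factors transcribed directly from the published trimmed-mean-of-M
# method: reference = sample whose upper-quartile count fraction is closest
# to the mean; per sample, weighted mean of log2 ratios after trimming 30%
# of M-values and 5% of A-values, weights = inverse delta-method variances;
# factors rescaled to geometric mean 1.
oracle_tmm_factors <- function(counts) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) unname(stats::quantile(counts[, j], 0.75)) / lib[j],
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  y_r <- counts[, ref] / lib[ref]
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    y_o <- counts[, j] / lib[j]
    use <- y_o > 0 & y_r > 0
    M <- log2(y_o[use] / y_r[use])
    A <- (log2(y_o[use]) + log2(y_r[use])) / 2
    w <- (lib[j] - counts[use, j]) / (lib[j] * counts[use, j]) +
      (lib[ref] - counts[use, ref]) / (lib[ref] * counts[use, ref])
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}

# Least-squares tree fit: for a fixed unrooted topology, solve for branch
# lengths minimizing sum over pairs of (path length - D)^2, and return the
# RSS and the fitted pairwise path-length matrix.
ls_fit_topology <- function(topo, D) {
  tips <- topo$tip.label
  npair <- utils::combn(length(tips), 2)
  A <- matrix(0, ncol(npair), nrow(topo$edge))
  d <- numeric(ncol(npair))
  for (k in seq_len(ncol(npair))) {
    i <- npair[1, k]; j <- npair[2, k]
    path <- ape::nodepath(topo, i, j)
    for (s in seq_len(length(path) - 1)) {
      e <- which((topo$edge[, 1] == path[s] & topo$edge[, 2] == path[s + 1]) |
                 (topo$edge[, 2] == path[s] & topo$edge[, 1] == path[s + 1]))
      A[k, e] <- 1
    }
    d[k] <- D[tips[i], tips[j]]
  }
  fit <- stats::lm.fit(A, d)
  list(rss = sum(fit$residuals^2), edge_lengths = fit$coefficients,
       fitted = A %*% fit$coefficients, pairs = npair)
}

# Brute-force best least-squares topology over all unrooted topologies
# (phangorn::allTrees enumerates them; the LS fit and selection are ours).
ls_best_tree <- function(D) {
  labels <- rownames(D)
  topos <- phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels)
  fits <- lapply(topos, ls_fit_topology, D = D)
  best <- which.min(vapply(fits, `[[`, numeric(1), "rss"))
  topo <- topos[[best]]
  topo$edge.length <- fits[[best]]$edge_lengths
  list(tree = topo, rss = fits[[best]]$rss)
}
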