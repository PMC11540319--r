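#' Rank-based inverse-normal phenotype preprocessing
#'
#' Fits an ordinary least-squares model of the raw trait on the
#' covariates (intercept included), then maps the residuals to standard
#' normal quantiles by rank. The default rank offset is Blom's
#' (`(r - 3/8) / (n + 1/4)`); ties get average ranks. Missing raw values
#' (or covariate rows) stay missing.
#'
#' @param raw numeric trait vector (NA = missing)
#' @param covariates optional numeric matrix/data.frame, rows aligned
#'   with `raw`
#' @param offset rank offset `c` in `(r - c) / (n - 2c + 1)` (default 3/8)
#' @return numeric vector of transformed values, NA where input was
#'   missing
#' @export
preprocess_phenotype <- function(raw, covariates = NULL, offset = 3 / 8) {
  n_all <- length(raw)
  keep <- !is.na(raw)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n_all) stop("covariates must align with the trait")
    keep <- keep & stats::complete.cases(covariates)
  }
  if (sum(keep) < 3) stop("need at least 3 non-missing values")
  y <- raw[keep]
  if (stats::sd(y) == 0) stop("constant trait")
  res <- if (is.null(covariates)) {
    y - mean(y)
  } else {
    stats::lm.fit(cbind(1, covariates[keep, , drop = FALSE]), y)$residuals
  }
  r <- rank(res, ties.method = "average")
  n <- length(r)
  z <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out <- rep(NA_real_, n_all)
  out[keep] <- z
  out
}

#' Encode haplogroup assignments as a SNP-style dosage
#'
#' The reference-like haplogroup is coded as homozygous reference (0)
#' and the other haplogroup as homozygous alternate (2); UNASSIGNED
#' samples are MISSING and excluded from association tests.
#'
#' @param assignments output of [assign_haplogroups()]
#' @param reference_like_group `"REF_GROUP"` or `"ALT_GROUP"`: the
#'   haplogroup that carries the reference-genome-like haplotype
#' @return named numeric vector in \{0, 2, NA\} per sample
#' @export
encode_haplotype <- function(assignments, reference_like_group = "REF_GROUP") {
  if (!reference_like_group %in% c("REF_GROUP", "ALT_GROUP"))
    stop("reference_like_group must be REF_GROUP or ALT_GROUP")
  other <- setdiff(c("REF_GROUP", "ALT_GROUP"), reference_like_group)
  x <- rep(NA_real_, nrow(assignments))
  x[assignments$label == reference_like_group] <- 0
  x[assignments$label == other] <- 2
  names(x) <- assignments$sample_id
  x
}

# internal: negative profiled REML log-likelihood at variance ratio gamma,
# on GRM-rotated data (ys = U'y, Xs = U'X, d = eigenvalues)
.reml_neg_loglik <- function(gamma, ys, Xs, d) {
  lam <- 1 + gamma * d
  w <- 1 / lam
  XtWX <- crossprod(Xs * w, Xs)
  XtWy <- crossprod(Xs * w, ys)
  ch <- chol(XtWX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  n <- length(ys); p <- ncol(Xs)
  0.5 * ((n - p) * log(rss) + sum(log(lam)) + 2 * sum(log(diag(ch))))
}

#' REML variance components under a GRM random effect
#'
#' Fits `y = X beta + g + e` with `g ~ N(0, sigma_g^2 * K)` and
#' `e ~ N(0, sigma_e^2 * I)` by restricted maximum likelihood: the GRM is
#' spectrally decomposed once and the profiled REML criterion is
#' optimized in one dimension over the variance ratio
#' `gamma = sigma_g^2 / sigma_e^2` (on a log grid bracket, boundary
#' `gamma = 0` included). Estimates are nonnegative by construction.
#'
#' @param y numeric response (no NAs; subset beforehand)
#' @param X fixed-effect design matrix (default intercept only)
#' @param grm a `grm` object from [compute_grm()] or a plain symmetric
#'   matrix aligned with `y`
#' @param eig optional precomputed `eigen()` of the GRM (symmetric), to
#'   reuse across traits
#' @return list: `sigma_g2`, `sigma_e2`, `gamma`, `loglik` (profiled, up
#'   to a constant), `n`, `eig`
#' @export
reml_variance_components <- function(y, X = NULL, grm, eig = NULL) {
  K <- if (inherits(grm, "grm")) grm$A else grm
  n <- length(y)
  if (nrow(K) != n) stop("GRM dimension does not match y")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  if (stats::sd(d) < 1e-8)
    stop("GRM is proportional to the identity: sigma_g^2 and sigma_e^2 are not separately identifiable")
  ys <- crossprod(eig$vectors, y)
  Xs <- crossprod(eig$vectors, X)

  f <- function(lg) .reml_neg_loglik(exp(lg), ys, Xs, d)
  opt <- stats::optimize(f, c(-12, 8), tol = 1e-8)
  f0 <- .reml_neg_loglik(0, ys, Xs, d)
  if (f0 <= opt$objective) {
    gamma <- 0; obj <- f0
  } else {
    gamma <- exp(opt$minimum); obj <- opt$objective
  }
  # recover sigma_e^2 at the optimum
  lam <- 1 + gamma * d
  w <- 1 / lam
  XtWX <- crossprod(Xs * w, Xs)
  beta <- solve(XtWX, crossprod(Xs * w, ys))
  rss <- sum(w * (ys - Xs %*% beta)^2)
  sigma_e2 <- rss / (n - ncol(Xs))
  list(sigma_g2 = gamma * sigma_e2, sigma_e2 = sigma_e2, gamma = gamma,
       loglik = -obj, n = n, eig = eig)
}

#' Mixed-linear-model association test (haplotype-as-SNP)
#'
#' Tests a single encoded variant against a processed phenotype by
#' generalized least squares with covariance
#' `V = sigma_g^2 * K + sigma_e^2 * I` held fixed at the null-model REML
#' estimates (variance components estimated once per trait without the
#' tested variant, then reused), giving a 1-df Wald chi-square p-value.
#'
#' @param y processed phenotype (NAs allowed; dropped with the matching
#'   rows of `x`, covariates and GRM)
#' @param x encoded haplotype dosage in \{0, 2, NA\}
#' @param grm a `grm` object or matrix over all samples in `y`
#' @param covariates optional fixed covariates
#' @param vc optional precomputed null variance components (from
#'   [reml_variance_components()] on exactly the analysis subset)
#' @param eig optional eigen decomposition matching the analysis subset
#' @return one-row data frame: n, beta, se, stat, p, sigma_g2, sigma_e2,
#'   flagged (TRUE when `x` is constant: effect undefined, no p-value)
#' @export
mlma_test <- function(y, x, grm, covariates = NULL, vc = NULL, eig = NULL) {
  K <- if (inherits(grm, "grm")) grm$A else grm
  keep <- !is.na(y) & !is.na(x)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  yk <- y[keep]; xk <- x[keep]
  Xnull <- if (is.null(covariates)) matrix(1, sum(keep), 1) else
    cbind(1, covariates[keep, , drop = FALSE])
  if (length(unique(xk)) < 2) {
    return(data.frame(n = sum(keep), beta = NA_real_, se = NA_real_,
                      stat = NA_real_, p = NA_real_, sigma_g2 = NA_real_,
                      sigma_e2 = NA_real_, flagged = TRUE))
  }
  Kk <- K[keep, keep, drop = FALSE]
  if (is.null(vc)) vc <- reml_variance_components(yk, Xnull, Kk, eig = eig)
  eig <- vc$eig
  d <- pmax(eig$values, 0)
  w <- 1 / (vc$sigma_e2 * (1 + vc$gamma * d))
  W <- cbind(Xnull, x = xk)
  Ws <- crossprod(eig$vectors, W)
  ys <- crossprod(eig$vectors, yk)
  WtVW <- crossprod(Ws * w, Ws)
  beta <- solve(WtVW, crossprod(Ws * w, ys))
  covb <- solve(WtVW)
  j <- ncol(W)
  se <- sqrt(covb[j, j])
  stat <- (beta[j] / se)^2
  data.frame(n = sum(keep), beta = beta[j], se = se, stat = stat,
             p = stats::pchisq(stat, 1, lower.tail = FALSE),
             sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2, flagged = FALSE)
}

#' Mixed-model PheWAS scan over many traits
#'
#' Runs [mlma_test()] for every trait column, reusing one spectral
#' decomposition of the GRM for all traits with complete data (traits
#' with missing values fall back to a per-trait decomposition of the
#' subset GRM).
#'
#' @param traits samples x traits matrix of processed phenotypes
#' @param x encoded haplotype dosage
#' @param grm a `grm` object or matrix
#' @param covariates optional covariates
#' @return data frame with one row per trait (trait, n, beta, se, stat,
#'   p, q, sigma_g2, sigma_e2, flagged); q-values are BH across all
#'   non-flagged traits
#' @export
mlma_scan <- function(traits, x, grm, covariates = NULL) {
  K <- if (inherits(grm, "grm")) grm$A else grm
  base_keep <- !is.na(x)
  if (!is.null(covariates))
    base_keep <- base_keep & stats::complete.cases(as.matrix(covariates))
  eig_full <- NULL
  rows <- vector("list", ncol(traits))
  for (j in seq_len(ncol(traits))) {
    y <- traits[, j]
    keep <- base_keep & !is.na(y)
    if (identical(which(keep), which(base_keep))) {
      if (is.null(eig_full))
        eig_full <- eigen(K[base_keep, base_keep, drop = FALSE], symmetric = TRUE)
      res <- mlma_test(y[base_keep], x[base_keep],
                       K[base_keep, base_keep, drop = FALSE],
                       covariates = if (is.null(covariates)) NULL else
                         as.matrix(covariates)[base_keep, , drop = FALSE],
                       eig = eig_full)
    } else {
      res <- mlma_test(y, x, K, covariates = covariates)
    }
    rows[[j]] <- res
  }
  out <- do.call(rbind, rows)
  out <- cbind(trait = colnames(traits) %||% paste0("trait", seq_len(ncol(traits))),
               out)
  out$q <- NA_real_
  ok <- !out$flagged & !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Naive per-trait ordinary least squares scan
#'
#' The no-GRM comparator: each trait is regressed on the encoded
#' haplotype (plus covariates) by OLS, ignoring relatedness. Used to
#' demonstrate inflation under family-confounded structure.
#'
#' @param traits samples x traits matrix
#' @param x encoded haplotype dosage
#' @param covariates optional covariates
#' @return data frame: trait, beta, p
#' @export
ols_scan <- function(traits, x, covariates = NULL) {
  keep <- !is.na(x)
  if (!is.null(covariates))
    keep <- keep & stats::complete.cases(as.matrix(covariates))
  X0 <- if (is.null(covariates)) matrix(1, sum(keep), 1) else
    cbind(1, as.matrix(covariates)[keep, , drop = FALSE])
  xk <- x[keep]
  # Frisch-Waugh: residualize x and each trait on the covariates
  qx <- qr(X0)
  rx <- qr.resid(qx, xk)
  Y <- traits[keep, , drop = FALSE]
  Y[is.na(Y)] <- NA  # keep NAs explicit; complete traits expected here
  RY <- qr.resid(qx, Y)
  sxx <- sum(rx^2)
  beta <- as.vector(crossprod(RY, rx)) / sxx
  n <- length(xk); pfix <- ncol(X0)
  rss <- colSums(RY^2) - beta^2 * sxx
  se <- sqrt(rss / (n - pfix - 1) / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - pfix - 1, lower.tail = FALSE)
  data.frame(trait = colnames(traits) %||% paste0("trait", seq_len(ncol(traits))),
             beta = beta, p = p)
}

#' Genomic-control inflation factor
#'
#' Lambda: the median of the 1-df chi-square statistics implied by the
#' p-values, divided by the null median chi-square.
#'
#' @param p vector of p-values
#' @return lambda
#' @export
genomic_lambda <- function(p) {
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p p-values in (0, 1]
#' @return q-values in input order (empty input gives empty output)
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Hypergeometric tail probability in the stated direction. A table with
#' a zero margin carries no information: p = 1, flagged.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#' @param direction "greater" or "less" (association direction for the
#'   \[1,1\] cell)
#' @return list: `p`, `flagged`
#' @export
fisher_one_sided <- function(table, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != round(table)))
    stop("need a 2x2 table of nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, flagged = TRUE))
  list(p = stats::fisher.test(table, alternative = direction)$p.value,
       flagged = FALSE)
}
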