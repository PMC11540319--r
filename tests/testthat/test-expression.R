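test_that("gene detection filter applies the strict less-than rule", {
  counts <- matrix(0L, 3, 100, dimnames = list(c("g9", "g10", "g0"), NULL))
  counts["g9", 1:9] <- 5L     # detected in 9% -> excluded
  counts["g10", 1:10] <- 5L   # detected in 10% -> retained
  kept <- filter_genes(counts)
  expect_equal(rownames(kept), "g10")
})

test_that("TMM factors are 1 for identical compositions and absorb library size", {
  base <- c(50, 100, 200, 10, 400, 80)
  counts <- cbind(a = base, b = base, c = base)
  out <- tmm_normalize(counts)
  expect_equal(unname(out$factors), rep(1, 3), tolerance = 1e-12)
  counts2 <- cbind(a = base, b = 2 * base, c = base)
  out2 <- tmm_normalize(counts2)
  expect_equal(unname(out2$factors), rep(1, 3), tolerance = 1e-12)
  expect_equal(out2$cpm[, "a"], out2$cpm[, "b"], tolerance = 1e-12)
  expect_error(tmm_normalize(cbind(a = c(0, 0), b = c(1, 2))), "zero library")
})

test_that("TMM matches an independent transcription of the published formula", {
  set.seed(61)
  for (i in 1:3) {
    counts <- matrix(rnbinom(200 * 6, mu = exp(runif(200, 2, 6)), size = 5) + 1L,
                     200, 6, dimnames = list(NULL, paste0("s", 1:6)))
    out <- tmm_normalize(counts)
    expect_equal(unname(out$factors), oracle_tmm_factors(counts),
                 tolerance = 1e-8)
    expect_equal(exp(mean(log(out$factors))), 1, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact and approximate branches behave as specified", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$U), 0)
  expect_true(res$exact)
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$p, oracle_mw_twosided(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  # ties force the corrected normal approximation
  tied <- mann_whitney(c(1, 2), c(1, 2))
  expect_false(tied$exact)
  expect_gt(tied$p, 0.99)
  # symmetry: swapping groups preserves p
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$p, res$p, tolerance = 1e-12)
  big <- mann_whitney(rnorm(30), rnorm(30))
  expect_false(big$exact)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney exact p agrees with labeling enumeration on small cases", {
  set.seed(62)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(mann_whitney(a, b)$p, oracle_mw_twosided(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney rejection rate is nominal under the null", {
  set.seed(63)
  rej <- mean(replicate(2000, mann_whitney(rnorm(50), rnorm(50))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.01)
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  hap <- rep(c("REF_GROUP", "ALT_GROUP"), each = 30)
  ex <- simulate_expression(hap, n_genes = 40, de_genes = c(g2 = 1.6), seed = 64)
  norm <- tmm_normalize(ex$counts)
  for (g in c("g1", "g2", "g3")) {
    v <- norm$cpm[g, ]
    p_raw <- mann_whitney(v[hap == "REF_GROUP"], v[hap == "ALT_GROUP"])$p
    lv <- log1p(v)
    p_log <- mann_whitney(lv[hap == "REF_GROUP"], lv[hap == "ALT_GROUP"])$p
    expect_equal(p_raw, p_log, tolerance = 1e-12)
  }
})

test_that("de_scan finds a planted fold change and pools BH across tissues", {
  hap <- rep(c("REF_GROUP", "ALT_GROUP"), each = 100)
  asg <- data.frame(sample_id = paste0("S", 1:200), label = hap)
  ex1 <- simulate_expression(hap, n_genes = 80, de_genes = c(g7 = 2), seed = 65)
  ex2 <- simulate_expression(hap, n_genes = 80, seed = 66)
  res <- de_scan(list(brain = ex1$counts, liver = ex2$counts), asg, "Y")
  brain <- res[res$tissue == "brain", ]
  expect_equal(brain$gene[which.min(brain$p)], "g7")
  expect_lt(res$q[res$gene == "g7" & res$tissue == "brain"], 0.05)
  # q is a deterministic function of the pooled p multiset
  expect_equal(res$q, oracle_bh(res$p), tolerance = 1e-12)
  per_tissue <- de_scan(list(brain = ex1$counts, liver = ex2$counts), asg, "Y",
                        pooling = "per_tissue")
  liver <- per_tissue[per_tissue$tissue == "liver", ]
  expect_equal(liver$q, oracle_bh(liver$p), tolerance = 1e-12)
})

test_that("samples without a haplogroup assignment are excluded before testing", {
  hap <- c(rep("REF_GROUP", 40), rep("ALT_GROUP", 40), rep(NA, 20))
  sex <- c(rep("male", 80), rep("female", 20))
  ex <- simulate_expression(hap, sex, n_genes = 30,
                            male_specific_genes = "g5", seed = 67)
  # females have no Y assignment: label them UNASSIGNED
  asg <- data.frame(sample_id = colnames(ex$counts),
                    label = ifelse(is.na(hap), "UNASSIGNED", hap))
  res <- de_scan(ex$counts, asg, "Y", tissue = "brain")
  expect_true(all(res$n_ref == 40 & res$n_alt == 40))
  # with only one group present the tissue is skipped
  asg_one <- asg; asg_one$label[asg_one$label == "ALT_GROUP"] <- "UNASSIGNED"
  expect_warning(res_one <- de_scan(ex$counts, asg_one, "Y"), "single haplogroup")
  expect_equal(nrow(res_one), 0)
})

test_that("X-SNP scan enforces the carrier threshold and matches closed-form OLS", {
  set.seed(68)
  n <- 20
  g_common <- rbinom(n, 2, 0.45)
  g_rare <- c(rep(1, 4), rep(0, n - 4))     # 4 carriers -> absent from output
  geno <- cbind(common = g_common, rare = g_rare)
  rownames(geno) <- paste0("S", 1:n)
  expr <- 0.7 * g_common + rnorm(n)
  res <- xsnp_linear_scan(expr, geno, sex = rep("female", n))
  expect_false("rare" %in% res$snp)
  fit <- summary(stats::lm(expr ~ g_common))
  row <- res[res$snp == "common", ]
  expect_equal(row$slope, fit$coefficients["g_common", "Estimate"],
               tolerance = 1e-10)
  expect_equal(row$p, fit$coefficients["g_common", "Pr(>|t|)"],
               tolerance = 1e-10)
  # a perfectly linear response gives the exact slope and a vanishing p
  expr2 <- 2 * g_common + 1
  res2 <- xsnp_linear_scan(expr2, geno[, "common", drop = FALSE],
                           sex = rep("female", n))
  expect_equal(res2$slope, 2, tolerance = 1e-10)
  expect_lt(res2$p, 1e-12)
})

test_that("male stratum includes the Y-haplogroup covariate", {
  set.seed(69)
  n <- 60
  sex <- rep(c("male", "female"), each = n / 2)
  hap <- c(rep(c("REF_GROUP", "ALT_GROUP"), n / 4), rep(NA, n / 2))
  geno <- cbind(x1 = rbinom(n, 2, 0.4))
  rownames(geno) <- paste0("S", 1:n)
  asg <- data.frame(sample_id = paste0("S", 1:(n / 2)),
                    label = hap[1:(n / 2)])
  hap_num <- ifelse(hap == "ALT_GROUP", 2, 0)
  expr <- 0.5 * geno[, 1] + 0.8 * ifelse(is.na(hap_num), 0, hap_num) + rnorm(n)
  res <- xsnp_linear_scan(expr, geno, sex, y_assignments = asg)
  male <- res[res$stratum == "male", ]
  idx <- 1:(n / 2)
  fit <- summary(stats::lm(expr[idx] ~ geno[idx, 1] + hap_num[idx]))
  expect_equal(male$slope, fit$coefficients[2, "Estimate"], tolerance = 1e-10)
  expect_equal(male$p, fit$coefficients[2, "Pr(>|t|)"], tolerance = 1e-10)
})
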