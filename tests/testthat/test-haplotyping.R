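test_that("allele counts partition the variant set per sample", {
  gm <- gm_from_strings(c(S1 = "RRA.", S2 = "...."))
  ac <- count_alleles(gm)
  expect_equal(unlist(ac[1, c("n_ref", "n_alt", "n_missing")], use.names = FALSE),
               c(2L, 1L, 1L))
  expect_equal(unlist(ac[2, c("n_ref", "n_alt", "n_missing")], use.names = FALSE),
               c(0L, 0L, 4L))
  expect_true(all(rowSums(ac[, c("n_ref", "n_alt", "n_missing")]) == 4))
  # summed per-sample counts equal matrix-wide tallies
  panel <- simulate_founder_haplotypes(n_sites = 200, d_between = 120,
                                       d_within = 3, seed = 13)
  pop <- simulate_population(panel, n_samples = 40, seed = 13)
  m <- mask_hemizygous_hets(pop$matrix)$matrix
  ac2 <- count_alleles(m)
  expect_equal(sum(ac2$n_ref), sum(m$calls == 0L, na.rm = TRUE))
  expect_equal(sum(ac2$n_alt), sum(m$calls == 2L, na.rm = TRUE))
  expect_equal(sum(ac2$n_missing), sum(is.na(m$calls)))
  expect_error(count_alleles(gm_from_strings("RHA")), "HET")
})

test_that("haplogroup labels follow the strict-majority rule, ties unassigned", {
  counts <- data.frame(sample_id = c("a", "b", "c"),
                       n_ref = c(10L, 2L, 3L), n_alt = c(2L, 10L, 3L),
                       n_missing = c(0L, 0L, 6L))
  asg <- assign_haplogroups(counts)
  expect_equal(asg$label, c("REF_GROUP", "ALT_GROUP", "UNASSIGNED"))
})

test_that("group labels conserve the sample count", {
  panel <- simulate_founder_haplotypes(n_sites = 300, d_between = 200,
                                       d_within = 0, seed = 14)
  pop <- simulate_population(panel, n_samples = 100, seed = 14)
  asg <- assign_haplogroups(count_alleles(mask_hemizygous_hets(pop$matrix)$matrix))
  expect_equal(sum(table(factor(asg$label,
                                c("REF_GROUP", "ALT_GROUP", "UNASSIGNED")))), 100)
})

test_that("assignment recovers the true haplogroup on noisy low-coverage data", {
  panel <- simulate_founder_haplotypes(n_sites = 4000, d_between = 3000,
                                       d_within = 10, seed = 15)
  pop <- simulate_population(panel, n_samples = 500, missing_rate_mean = 0.5,
                             missing_rate_sd = 0.05, het_error_rate = 0.01,
                             seed = 15)
  m <- mask_hemizygous_hets(pop$matrix)$matrix
  asg <- assign_haplogroups(count_alleles(m))
  acc <- mean(asg$label == pop$truth$haplogroup)
  expect_gte(acc, 0.999)
})

test_that("consensus takes the modal call and leaves ties/empty columns missing", {
  gm <- gm_from_strings(c(S1 = "AAR", S2 = "A.A", S3 = ".RA"))
  asg <- data.frame(sample_id = c("S1", "S2", "S3"),
                    label = c("ALT_GROUP", "ALT_GROUP", "ALT_GROUP"))
  cons <- consensus_genotypes(gm, asg, "ALT_GROUP")
  # col1: {A,A} -> ALT; col2: {A,R} tie -> MISSING; col3: {R,A,A} -> ALT
  expect_equal(as.integer(cons), c(2L, NA_integer_, 2L))
  expect_error(consensus_genotypes(gm, asg, "REF_GROUP"), "no samples")
})

test_that("unassigned samples never contribute to the consensus", {
  panel <- simulate_founder_haplotypes(n_sites = 300, d_between = 200,
                                       d_within = 0, seed = 16)
  pop <- simulate_population(panel, n_samples = 80, missing_rate_mean = 0.5,
                             het_error_rate = 0.02, seed = 16)
  m <- mask_hemizygous_hets(pop$matrix)$matrix
  asg <- assign_haplogroups(count_alleles(m))
  cons_all <- consensus_genotypes(m, asg, "REF_GROUP")
  asg_only <- asg[asg$label != "UNASSIGNED", ]
  cons_no_un <- consensus_genotypes(m, asg_only, "REF_GROUP")
  expect_identical(as.integer(cons_all), as.integer(cons_no_un))
})

test_that("noiseless consensus reproduces the contributing founder exactly", {
  panel <- simulate_founder_haplotypes(n_sites = 500, d_between = 350,
                                       d_within = 4, seed = 17)
  pop <- simulate_population(panel, n_samples = 60, missing_rate_mean = 0,
                             missing_rate_sd = 0, het_error_rate = 0, seed = 17)
  asg <- assign_haplogroups(count_alleles(pop$matrix))
  for (grp in c("REF_GROUP", "ALT_GROUP")) {
    cons <- consensus_genotypes(pop$matrix, asg, grp)
    founder <- unique(pop$truth$founder[pop$truth$haplogroup == grp])
    expect_length(founder, 1)
    expect_equal(as.integer(cons), unname(panel$calls[founder, ]))
    m <- match_founders(cons, panel)
    expect_equal(m$best, founder)
    expect_false(m$tie)
    expect_equal(m$distances$n_diff[m$distances$founder == founder], 0)
  }
})

test_that("founder matching reports distances and flags exact ties", {
  cons <- consensus_genotypes(
    gm_from_strings(c(S1 = "RRRR", S2 = "RRRR")),
    data.frame(sample_id = c("S1", "S2"), label = "REF_GROUP"), "REF_GROUP")
  panel <- gm_from_strings(c(FA = "RRRR", FB = "RRAA", FC = "AARR"))
  m <- match_founders(cons, panel)
  expect_equal(m$best, "FA")
  expect_equal(m$distances$distance, c(0, 0.5, 0.5))
  panel2 <- gm_from_strings(c(FB = "RRRA", FC = "ARRR"))
  m2 <- match_founders(cons, panel2)
  expect_true(m2$tie)
  expect_setequal(m2$best, c("FB", "FC"))
  # a founder with no comparable site is incomparable, not distance zero
  panel3 <- gm_from_strings(c(FA = "RRRR", FD = "...."))
  m3 <- match_founders(cons, panel3)
  expect_true(is.na(m3$distances$distance[m3$distances$founder == "FD"]))
})

test_that("intragroup variation counts planted mutations and is missingness-monotone", {
  panel <- simulate_founder_haplotypes(n_sites = 400, d_between = 300,
                                       d_within = 0, seed = 18)
  pop <- simulate_population(panel, n_samples = 100, missing_rate_mean = 0,
                             missing_rate_sd = 0, het_error_rate = 0, seed = 18)
  m <- pop$matrix
  # plant one mutation in 10 known samples
  mutated <- paste0("S", 1:10)
  flip_site <- 5L
  m$calls[mutated, flip_site] <- 2L - m$calls[mutated, flip_site]
  asg <- assign_haplogroups(count_alleles(m))
  for (grp in c("REF_GROUP", "ALT_GROUP")) {
    cons <- consensus_genotypes(m, asg, grp)
    iv <- intragroup_variation(m, asg, cons, grp)
    in_grp <- iv$per_sample$sample_id %in% mutated
    expect_true(all(iv$per_sample$n_mismatch[in_grp] == 1))
    expect_true(all(iv$per_sample$n_mismatch[!in_grp] == 0))
  }
  # masking a site can never increase a mismatch count
  grp <- asg$label[asg$sample_id == "S1"]
  cons <- consensus_genotypes(m, asg, grp)
  before <- intragroup_variation(m, asg, cons, grp)
  m2 <- m
  m2$calls["S1", flip_site] <- NA_integer_
  after <- intragroup_variation(m2, asg, cons, grp)
  i <- before$per_sample$sample_id == "S1"
  expect_lte(after$per_sample$n_mismatch[i], before$per_sample$n_mismatch[i])
})

test_that("the two group consensuses differ at the designed between-group sites", {
  panel <- simulate_founder_haplotypes(n_sites = 1000, d_between = 700,
                                       d_within = 5, seed = 19)
  pop <- simulate_population(panel, n_samples = 400, missing_rate_mean = 0.4,
                             het_error_rate = 0.01, seed = 19)
  m <- mask_hemizygous_hets(pop$matrix)$matrix
  asg <- assign_haplogroups(count_alleles(m))
  cr <- consensus_genotypes(m, asg, "REF_GROUP")
  ca <- consensus_genotypes(m, asg, "ALT_GROUP")
  between <- attr(panel, "between_sites")
  both_called <- which(!is.na(cr) & !is.na(ca))
  div_at_between <- sum(cr[both_called] != ca[both_called] &
                          both_called %in% between)
  expect_equal(div_at_between, sum(between %in% both_called))
})
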