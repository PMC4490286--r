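test_that("default group sizes produce a 306-subject cohort with full metadata", {
  cfg <- cohort_config(n_snps = 80, n_features = 24, k_geno = 2, k_eeg = 2,
                       seed = 3)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$genotypes$dosage), 306)
  expect_equal(as.integer(table(ch$genotypes$subjects$group)[c("control",
                                                               "case1",
                                                               "case2")]),
               c(56L, 105L, 145L))
  expect_equal(ncol(ch$genotypes$dosage), 80)
  expect_equal(ncol(ch$features$weights), 24)
  expect_true(all(c("age", "sex", "site", "ethnicity") %in%
                    names(ch$genotypes$subjects)))
  expect_true(all(is.na(ch$genotypes$subjects$panss_pos[
    ch$genotypes$subjects$group == "control"])))
})

test_that("invalid config fields raise errors naming the field", {
  expect_error(cohort_config(n_snps = 0), "n_snps")
  expect_error(cohort_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(coupled_pairs = list(list(geno = 1, eeg = 1,
                                                       r = 1.2))),
               "coupled_pairs")
  expect_error(cohort_config(fst = -0.1), "fst")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- cohort_config(n_per_group = c(15, 15, 15), n_snps = 60,
                       n_features = 20, k_geno = 2, k_eeg = 2,
                       missing_rate = 0.02, fst = 0.05, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$features$weights, b$features$weights)
  expect_identical(a$truth$geno_loadings, b$truth$geno_loadings)
  expect_identical(a$genotypes$subjects, b$genotypes$subjects)
})

test_that("coupled truth loadings hit the designed correlation", {
  # Fisher-z sampling interval at n = 2000: 0.5 +/- ~0.05
  cfg <- cohort_config(n_per_group = c(700, 650, 650), n_snps = 4,
                       n_features = 4, k_geno = 2, k_eeg = 2,
                       coupled_pairs = list(list(geno = 1, eeg = 1,
                                                 r = 0.5)),
                       seed = 7)
  ch <- generate_cohort(cfg)
  r_emp <- cor(ch$truth$geno_loadings[, 1], ch$truth$eeg_loadings[, 1])
  expect_lt(abs(r_emp - 0.5), 0.05)
})

test_that("designed r = 1 makes the standardized pair identical and r = 0 independent", {
  cfg1 <- cohort_config(n_per_group = c(40, 40, 40), n_snps = 4,
                        n_features = 4, k_geno = 1, k_eeg = 1,
                        coupled_pairs = list(list(geno = 1, eeg = 1, r = 1)),
                        seed = 5)
  ch1 <- generate_cohort(cfg1)
  expect_equal(ch1$truth$geno_loadings[, 1], ch1$truth$eeg_loadings[, 1],
               tolerance = 1e-12)
  cfg0 <- cohort_config(n_per_group = c(4000, 3000, 3000), n_snps = 4,
                        n_features = 4, k_geno = 1, k_eeg = 1,
                        coupled_pairs = list(list(geno = 1, eeg = 1, r = 0)),
                        seed = 6)
  ch0 <- generate_cohort(cfg0)
  expect_lt(abs(cor(ch0$truth$geno_loadings[, 1],
                    ch0$truth$eeg_loadings[, 1])), 0.05)
})

test_that("genotypes are binomial with mean 2p and pass HWE when unstructured", {
  g <- simulate_genotypes(maf = 0.3, n_subjects = 10000, seed = 1)
  se <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(g) - 0.6), 3 * se)
  # null SNPs pass the HWE exact test at alpha = 1e-5 nearly always
  set.seed(2)
  gm <- simulate_genotypes(maf = runif(2000, 0.1, 0.5), n_subjects = 400,
                           seed = 3)
  pvals <- apply(gm, 2, function(g)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)))
  expect_gte(mean(pvals >= 1e-5), 0.99)
})

test_that("MAF outside (0, 0.5] is rejected", {
  expect_error(simulate_genotypes(maf = c(0.3, 0.6), n_subjects = 10),
               "maf")
  expect_error(simulate_genotypes(maf = 0, n_subjects = 10), "maf")
})

test_that("two-subpopulation structure drives the leading genotype PC", {
  cfg <- cohort_config(n_per_group = c(60, 60, 60), n_snps = 500,
                       n_features = 8, k_geno = 2, k_eeg = 2,
                       fst = 0.1, missing_rate = 0, seed = 9)
  ch <- generate_cohort(cfg)
  X <- scale(ch$genotypes$dosage)
  X[is.na(X)] <- 0
  pc1 <- svd(X, nu = 1, nv = 0)$u[, 1]
  r_pb <- cor(pc1, as.numeric(ch$truth$subpop_labels == 2))
  expect_gt(abs(r_pb), 0.5)
})

test_that("group shifts make the latent loadings separable between groups", {
  shift <- matrix(c(0, 1, 1), nrow = 1)   # cases shifted +1 sd
  cfg <- cohort_config(n_per_group = c(60, 60, 60), n_snps = 4,
                       n_features = 4, k_geno = 1, k_eeg = 1,
                       group_shift = list(geno = shift), seed = 13)
  ch <- generate_cohort(cfg)
  g <- ch$truth$group_labels
  tt <- t.test(ch$truth$geno_loadings[g == "control", 1],
               ch$truth$geno_loadings[g != "control", 1])
  expect_lt(tt$p.value, 0.01)
})

test_that("injected LD duplicates and duplicate subjects are present", {
  cfg <- cohort_config(n_per_group = c(20, 20, 20), n_snps = 120,
                       n_features = 8, k_geno = 2, k_eeg = 2,
                       missing_rate = 0, n_ld_duplicate_pairs = 3,
                       n_duplicate_subjects = 2, seed = 21)
  ch <- generate_cohort(cfg)
  R2 <- suppressWarnings(cor(ch$genotypes$dosage))^2
  diag(R2) <- 0
  expect_gte(sum(R2 > 0.999, na.rm = TRUE) / 2, 3)
  D <- as.matrix(dist(ch$genotypes$dosage))
  diag(D) <- Inf
  expect_gte(sum(D == 0) / 2, 2)
})
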