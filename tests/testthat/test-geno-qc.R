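test_that("additive coding counts minor alleles", {
  expect_equal(code_additive("CC", "A", "C"), 2L)
  expect_equal(code_additive("AA", "A", "C"), 0L)
  expect_equal(code_additive(c("AC", "CA"), "A", "C"), c(1L, 1L))
  expect_true(is.na(code_additive("00", "A", "C")))
  expect_true(is.na(code_additive(NA_character_, "A", "C")))
  expect_error(code_additive("AG", "A", "C"), "allele")
})

test_that("HWE exact test matches enumeration and handles edge cases", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(3, 4, 3), hwe_enumeration_oracle(3, 4, 3),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 3), "counts")
  # random spot checks across sample sizes
  set.seed(11)
  for (i in 1:200) {
    x <- as.vector(rmultinom(1, sample(1:80, 1), runif(3)))
    expect_equal(hwe_exact_test(x[1], x[2], x[3]),
                 hwe_enumeration_oracle(x[1], x[2], x[3]),
                 tolerance = 1e-10)
  }
})

test_that("a strongly HWE-deviant SNP is excluded at the 1e-5 threshold", {
  # all-heterozygote genotypes in controls: exact P far below 1e-5
  n <- 120
  doz <- cbind(rep(1L, n),                       # HWE-violating
               rbinom(n, 2, 0.3))                # clean
  set.seed(4)
  doz[, 2] <- rbinom(n, 2, 0.3)
  gt <- toy_genotype_table(doz, groups = rep(c("control", "case1"),
                                             each = n / 2))
  expect_lt(hwe_exact_test(0, n / 2, 0), 1e-5)
  res <- snp_filters(gt, maf_min = 0, call_min = 0, diffmiss_alpha = 0)
  expect_false("s001" %in% res$table$snps$id)
  expect_true("s002" %in% res$table$snps$id)
})

test_that("sample QC removes high-missingness subjects and duplicate pairs", {
  set.seed(8)
  n <- 60; m <- 400
  doz <- matrix(rbinom(n * m, 2, rep(runif(m, 0.2, 0.5), each = n)), n, m)
  # subject 1: 5% missing; subject 2 duplicates subject 3
  doz[1, sample(m, round(0.05 * m))] <- NA
  doz[2, ] <- doz[3, ]
  gt <- toy_genotype_table(doz)
  res <- sample_qc(gt)
  kept <- res$table$subjects$id
  expect_false("i001" %in% kept)
  expect_equal(sum(c("i002", "i003") %in% kept), 1L)
  expect_gt(res$stats$max_relatedness[2], 0.9)
  # report arithmetic: remaining counts non-increasing, removals add up
  steps <- qc_entries_df <- do.call(rbind, lapply(res$entries, function(e)
    c(e$removed, e$remaining)))
  expect_true(all(diff(steps[, 2]) <= 0))
  expect_equal(n - sum(steps[, 1]), steps[nrow(steps), 2])
})

test_that("a clean unrelated cohort suffers no sample-QC removals", {
  set.seed(15)
  n <- 80; m <- 500
  doz <- matrix(rbinom(n * m, 2, rep(runif(m, 0.2, 0.5), each = n)), n, m)
  res <- sample_qc(toy_genotype_table(doz))
  expect_gte(nrow(res$table$dosage), n - 1)  # ~0.3% false het removals tolerated
})

test_that("SNP filters remove exactly the constructed failures", {
  set.seed(23)
  n <- 200
  groups <- rep(c("control", "case1"), each = n / 2)
  clean <- function() rbinom(n, 2, 0.3)
  doz <- cbind(rbinom(n, 2, 0.02),   # fails MAF < 5%
               clean(),              # fails call rate (below)
               rep(1L, n),           # fails HWE in controls
               clean(),              # fails differential missingness (below)
               clean(), clean())     # retained
  doz[sample(n, round(0.05 * n)), 2] <- NA
  doz[which(groups == "case1")[1:40], 4] <- NA
  gt <- toy_genotype_table(doz, groups = groups)
  res <- snp_filters(gt)
  expect_setequal(res$table$snps$id, c("s005", "s006"))
  steps <- sapply(res$entries, function(e) e$remaining)
  expect_true(all(diff(steps) <= 0))
})

test_that("a passing SNP is retained", {
  set.seed(30)
  doz <- matrix(rbinom(100 * 3, 2, 0.25), 100, 3)
  gt <- toy_genotype_table(doz)
  res <- snp_filters(gt)
  expect_equal(ncol(res$table$dosage), 3)
})

test_that("LD pruning drops perfect duplicates and keeps independent SNPs", {
  set.seed(31)
  n <- 100
  a <- rbinom(n, 2, 0.4)
  doz <- cbind(a, a, rbinom(n, 2, 0.4), rbinom(n, 2, 0.3))
  gt <- toy_genotype_table(doz, pos = c(1000L, 1100L, 5000L, 50000L))
  res <- ld_prune(gt)
  expect_setequal(res$table$snps$id, c("s001", "s003", "s004"))
})

test_that("LD pruning equals the brute-force all-pairs oracle on a correlated panel", {
  set.seed(33)
  n <- 120; m <- 60
  base <- matrix(rbinom(n * m, 2, rep(runif(m, 0.2, 0.5), each = n)), n, m)
  # correlated blocks: copy neighbors with flips at varying rates
  for (j in seq(2, m, by = 3)) {
    flip <- runif(n) < 0.08
    base[, j] <- ifelse(flip, rbinom(n, 2, 0.35), base[, j - 1])
  }
  chrom <- rep(1:2, each = m / 2)
  pos <- as.integer(rep(seq_len(m / 2), 2) * 2500)
  gt <- toy_genotype_table(base, chrom = chrom, pos = pos)
  res <- ld_prune(gt)
  keep_oracle <- ld_prune_bruteforce(base, chrom, pos)
  expect_identical(res$table$snps$id, gt$snps$id[keep_oracle])
  # no retained in-window pair above the ceiling
  kept <- which(keep_oracle)
  for (i in kept) for (j in kept) {
    if (j <= i || chrom[j] != chrom[i] || pos[j] - pos[i] > 10000) next
    r2 <- suppressWarnings(cor(base[, i], base[, j]))^2
    expect_lte(r2, 0.8 + 1e-12)
  }
})

test_that("stratification adjustment flags ancestry components and is idempotent", {
  cfg <- cohort_config(n_per_group = c(50, 50, 50), n_snps = 400,
                       n_features = 8, k_geno = 2, k_eeg = 2, fst = 0.1,
                       missing_rate = 0, seed = 17)
  ch <- generate_cohort(cfg)
  res <- stratification_adjust(ch$genotypes)
  expect_gte(length(res$flagged), 1)
  # after residualization the flagged components no longer track ethnicity
  eth <- factor(ch$genotypes$subjects$ethnicity)
  Z2 <- scale(res$adjusted)
  Z2[!is.finite(Z2)] <- 0
  sv <- svd(Z2, nu = 5, nv = 0)
  p_after <- anova(lm(sv$u[, 1] ~ eth))$`Pr(>F)`[1]
  expect_gt(p_after, 0.05)
  # idempotence: residualizing again on the same flagged scores is a no-op
  D <- cbind(1, res$scores[, res$flagged, drop = FALSE])
  twice <- res$adjusted - D %*% qr.coef(qr(D), res$adjusted)
  expect_lt(max(abs(twice - res$adjusted)), 1e-10)
})

test_that("stratification under the null flags about alpha of scanned components", {
  # pooled over seeds: expected flag rate = 5% under fst = 0
  flags <- 0; scanned <- 0
  for (s in 1:6) {
    cfg <- cohort_config(n_per_group = c(30, 30, 30), n_snps = 200,
                         n_features = 8, k_geno = 2, k_eeg = 2, fst = 0,
                         snp_effect_size = 0, missing_rate = 0, seed = 100 + s)
    ch <- generate_cohort(cfg)
    ch$genotypes$subjects$ethnicity <-
      sample(c("a", "b"), 90, replace = TRUE)
    res <- stratification_adjust(ch$genotypes)
    flags <- flags + length(res$flagged)
    scanned <- scanned + 10
  }
  expect_lte(flags, qbinom(0.999, scanned, 0.05))
})

test_that("single ethnicity category adjusts nothing and says so", {
  set.seed(41)
  doz <- matrix(rbinom(40 * 50, 2, 0.3), 40, 50)
  gt <- toy_genotype_table(doz)
  res <- stratification_adjust(gt)
  expect_length(res$flagged, 0)
  expect_match(res$entries[[1]]$detail, "single ethnicity")
})

test_that("prefilter has zero power on constant dosage and honors union semantics", {
  set.seed(51)
  n <- 150
  groups <- rep(c("control", "case1", "case2"), each = n / 3)
  X <- cbind(rep(1, n),                               # constant
             rnorm(n),                                # null
             ifelse(groups == "case2", 1.5, 0) + rnorm(n, sd = 0.3))
  colnames(X) <- c("flat", "null", "c2only")
  res <- univariate_prefilter(X, groups)
  expect_equal(res$stats$p[res$stats$id == "flat"], c(1, 1))
  expect_true("c2only" %in% res$selected)
  p_c1 <- res$stats$p[res$stats$id == "c2only" &
                        res$stats$contrast == "case1"]
  expect_gt(p_c1, 0.025)  # only the case2 contrast drives selection
})

test_that("perfect separation falls back to the score test and is flagged", {
  n <- 60
  groups <- rep(c("control", "case1"), each = n / 2)
  x <- ifelse(groups == "case1", 2, 0)
  X <- cbind(sep = x, null = rnorm(n))
  res <- univariate_prefilter(X, groups)
  row <- res$stats[res$stats$id == "sep", ]
  expect_true(all(row$separation))
  expect_true(all(is.finite(row$p)))
  expect_lt(row$p[1], 1e-6)
})
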