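test_that("MDL order: white noise gives 0, rank-1 gives 1, five sources give 5", {
  set.seed(1)
  expect_equal(estimate_order_mdl(matrix(rnorm(300 * 120), 300)), 0L)
  a <- rnorm(300); s <- rnorm(200)
  X1 <- outer(a, s) + matrix(rnorm(300 * 200, sd = 0.05 * sd(outer(a, s))),
                             300)
  expect_equal(estimate_order_mdl(X1), 1L)
  A <- matrix(rnorm(300 * 5), 300)
  S <- laplace_sources(5, 200)
  sig <- A %*% S
  X5 <- sig + matrix(rnorm(300 * 200, sd = sd(sig) / sqrt(10)), 300)
  expect_equal(estimate_order_mdl(X5), 5L)
})

test_that("MDL estimate converges to the true order with sample size", {
  ks <- sapply(c(100, 300, 1000), function(n) {
    set.seed(n)
    A <- matrix(rnorm(n * 3), n)
    S <- laplace_sources(3, 150)
    sig <- A %*% S
    estimate_order_mdl(sig + matrix(rnorm(n * 150, sd = sd(sig) / 3), n))
  })
  expect_equal(ks[3], 3L)
  expect_true(all(abs(ks - 3L) <= c(2L, 1L, 0L)))
})

test_that("constant data yields order 0", {
  expect_equal(estimate_order_mdl(matrix(1, 50, 30)), 0L)
})

test_that("stability selection finds the true order on separated sparse sources", {
  set.seed(3)
  n <- 150; p <- 600; ktrue <- 4
  A <- matrix(rnorm(n * ktrue), n)
  S <- matrix(0, ktrue, p)
  for (j in seq_len(ktrue)) {
    w <- rexp(30) * sample(c(-1, 1), 30, TRUE)
    S[j, ((j - 1) * 30 + 1):(j * 30)] <- 3 * w / sqrt(mean(w^2))
  }
  sig <- A %*% S
  X <- sig + matrix(rnorm(n * p, sd = sd(sig) / sqrt(10)), n)
  k <- estimate_order_stability(X, 2:6, n_runs = 6, seed = 5,
                                max_iter = 200)
  expect_equal(as.integer(k), 4L)
  expect_false(attr(k, "low_confidence"))
})

test_that("pure noise is flagged low-confidence", {
  set.seed(4)
  X <- matrix(rnorm(80 * 100), 80)
  k <- suppressWarnings(estimate_order_stability(X, 2:4, n_runs = 5,
                                                 seed = 2, max_iter = 100))
  expect_true(attr(k, "low_confidence"))
})

test_that("stability selection validates its candidates", {
  expect_error(estimate_order_stability(matrix(rnorm(40), 10),
                                        integer(0)), "k_candidates")
})

test_that("Infomax recovers super-Gaussian mixtures (Amari < 0.05)", {
  set.seed(6)
  S0 <- laplace_sources(3, 2000)
  A0 <- matrix(rnorm(9), 3)
  dec <- infomax_ica(A0 %*% S0, 3, seed = 7)
  expect_true(dec$converged)
  expect_lt(amari_index(dec$unmixing %*% A0), 0.05)
  # Z-maps standardized per component
  expect_equal(rowMeans(dec$zmaps), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(dec$zmaps, 1, sd), rep(1, 3), tolerance = 1e-10)
})

test_that("rank-1 data returns the generating source up to scale", {
  set.seed(8)
  a <- rnorm(400); s <- rexp(300) * sample(c(-1, 1), 300, TRUE)
  dec <- suppressWarnings(infomax_ica(outer(a, s), 1, seed = 2))
  expect_gt(abs(cor(dec$sources[1, ], s)), 0.999)
  expect_gt(abs(cor(dec$loadings[, 1], a)), 0.999)
})

test_that("whitened subspace reconstruction is numerically exact", {
  set.seed(9)
  X <- matrix(rnorm(60 * 40), 60) %*% diag(seq(1, 3, length.out = 40))
  dec <- suppressWarnings(infomax_ica(X, 5, seed = 3, max_iter = 200))
  recon <- dec$loadings %*% dec$sources
  Xc <- X - rowMeans(X)
  wh <- paricaeeg:::whiten_rows(X, 5)
  proj <- t(wh$dewhite %*% wh$K %*% Xc)   # retained-subspace part of Xc
  expect_lt(norm(t(recon) - proj, "F") / norm(proj, "F"), 1e-8)
})

test_that("k above the data rank is rejected", {
  X <- matrix(rnorm(20), 10, 2) %*% matrix(1, 2, 5)  # rank <= 2
  expect_error(infomax_ica(X, 4), "rank")
})

test_that("para_ica with zero coupling equals two independent Infomax runs bit for bit", {
  set.seed(10)
  X1 <- matrix(rnorm(70 * 50), 70); X2 <- matrix(rnorm(70 * 30), 70)
  pr <- para_ica(X1, X2, 3, 2, coupling = coupling_config(lambda_max = 0),
                 seed = 17, max_iter = 400)
  s <- fan_seeds(17, 2)
  d1 <- suppressWarnings(infomax_ica(X1, 3, seed = s[1], max_iter = 400))
  d2 <- suppressWarnings(infomax_ica(X2, 2, seed = s[2], max_iter = 400))
  expect_identical(pr$snp$loadings, d1$loadings)
  expect_identical(pr$snp$sources, d1$sources)
  expect_identical(pr$eeg$loadings, d2$loadings)
  expect_identical(pr$eeg$W, d2$W)
})

test_that("para_ica validates subject alignment and ranks", {
  expect_error(para_ica(matrix(rnorm(40), 10), matrix(rnorm(33), 11), 2, 2),
               "subjects")
})

test_that("coupling raises the recovered cross-correlation above the decoupled run", {
  cfg <- cohort_config(n_per_group = c(70, 70, 70), n_snps = 300,
                       n_features = 96, k_geno = 3, k_eeg = 3,
                       coupled_pairs = list(list(geno = 1, eeg = 1,
                                                 r = 0.5)),
                       snp_effect_size = 1.5, noise_sd = 0.3,
                       geno_sparsity = 0.15, missing_rate = 0, seed = 29)
  ch <- generate_cohort(cfg)
  X <- scale(ch$genotypes$dosage * 1.0)
  fe <- ch$features$weights
  coupled <- para_ica(X, fe, 3, 3, seed = 29, max_iter = 500)
  decoupled <- para_ica(X, fe, 3, 3,
                        coupling = coupling_config(lambda_max = 0),
                        seed = 29, max_iter = 500)
  expect_gt(max(abs(coupled$cross_corr)), 0.3)
  expect_gte(max(abs(coupled$cross_corr)) + 1e-6,
             max(abs(decoupled$cross_corr)))
  expect_true(all(abs(coupled$cross_corr) <= 1))
})

test_that("zscore_select ranks and thresholds a fixed Z map by hand enumeration", {
  z <- c(2.5, -2.1, 1.9, 0.5, -3.0, 2.0)
  dec <- list(zmaps = rbind(z))
  sel <- zscore_select(dec, z_threshold = 2,
                       feature_names = letters[1:6])[[1]]
  expect_equal(sel$z, c(-3.0, 2.5, -2.1, 2.0))
  expect_equal(sel$feature, c("e", "a", "b", "f"))
  expect_equal(sel$relative_weight[1], 1)
  expect_equal(sel$relative_weight, abs(sel$z) / 3.0)
  # below-threshold map selects nothing
  empty <- zscore_select(list(zmaps = rbind(c(1.5, -1.2, 0.3))), 2)[[1]]
  expect_equal(nrow(empty), 0)
})
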