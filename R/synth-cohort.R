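# Synthetic three-group cohort generator -------------------------------------
#
# Emulates a case/case/control imaging-genetics cohort: additive SNP dosages
# drawn under Hardy-Weinberg equilibrium (optionally with Balding-Nichols
# two-subpopulation structure), spatio-spectral EEG feature weights, and a
# set of latent components per modality whose subject loadings can be
# cross-correlated at a designed r and shifted by diagnosis group. The
# latent truth is returned alongside the data so recovery can be scored.

#' Configuration for a synthetic coupled cohort
#'
#' Defaults emulate a three-group multisite psychosis cohort: 56 controls
#' and 105 + 145 probands in two case groups, with realistic per-group
#' demographic distributions (age, sex, six collection sites, ethnicity,
#' symptom and medication scores), 2000 SNPs and 512 EEG spatio-spectral
#' features.
#'
#' @param n_per_group named integer vector `(control, case1, case2)`.
#' @param n_snps,n_features SNP and EEG feature counts.
#' @param k_geno,k_eeg number of latent components per modality.
#' @param coupled_pairs list of `list(geno=, eeg=, r=)` giving component
#'   indices and the designed cross-modal Pearson correlation in `[-1, 1]`.
#' @param group_shift list with optional `geno` and `eeg` matrices of size
#'   k x 3 (components x groups): standardized mean shift added to each
#'   latent loading per group. `NULL` means no shift.
#' @param maf_range minor-allele-frequency interval, a subset of (0, 0.5].
#' @param fst fixation index >= 0; positive values activate a
#'   two-subpopulation Balding-Nichols structure.
#' @param subpop_fractions length-2 fractions of subjects per subpopulation
#'   (used when `fst > 0`).
#' @param snp_effect_size logit-scale shift of the per-SNP minor-allele
#'   probability per unit (map weight x subject loading) for
#'   component-member SNPs.
#' @param noise_sd EEG feature noise standard deviation.
#' @param missing_rate genotype missingness probability in `[0, 1)`.
#' @param geno_sparsity fraction of SNPs in each genetic component's
#'   support (supports are disjoint across components when possible).
#' @param eeg_sparsity fraction of features in each EEG component's support.
#' @param n_ld_duplicate_pairs number of SNP pairs made into near-duplicate
#'   (perfect-LD) neighbors within 10 kb, for pruning tests.
#' @param n_duplicate_subjects number of subjects duplicated (genotype
#'   copies) to create related pairs, for relatedness-QC tests.
#' @param confound_strength optional confounding: standardized contribution
#'   of age and sex to every latent loading (0 = demographics independent
#'   of truth).
#' @param seed integer master seed; all outputs are a deterministic
#'   function of the config.
#' @return validated `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(control = 56, case1 = 105, case2 = 145),
                          n_snps = 2000, n_features = 512,
                          k_geno = 9, k_eeg = 5,
                          coupled_pairs = list(),
                          group_shift = NULL,
                          maf_range = c(0.05, 0.5),
                          fst = 0, subpop_fractions = c(0.5, 0.5),
                          snp_effect_size = 0.5,
                          noise_sd = 1,
                          missing_rate = 0.005,
                          geno_sparsity = 0.03,
                          eeg_sparsity = 0.15,
                          n_ld_duplicate_pairs = 0,
                          n_duplicate_subjects = 0,
                          confound_strength = 0,
                          seed = 1L) {
  if (length(n_per_group) != 3L || any(n_per_group < 1) ||
      any(n_per_group != round(n_per_group)))
    stop_field("n_per_group", "must be three positive subject counts")
  n_per_group <- as.integer(n_per_group)
  names(n_per_group) <- c("control", "case1", "case2")
  n_snps <- check_count(n_snps, "n_snps")
  n_features <- check_count(n_features, "n_features")
  k_geno <- check_count(k_geno, "k_geno")
  k_eeg <- check_count(k_eeg, "k_eeg")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_field("maf_range", "must be an interval within (0, 0.5]")
  check_scalar_in(fst, "fst", 0, 1, FALSE, TRUE)
  check_scalar_in(missing_rate, "missing_rate", 0, 1, FALSE, TRUE)
  check_scalar_in(noise_sd, "noise_sd", 0, Inf)
  check_scalar_in(snp_effect_size, "snp_effect_size", -Inf, Inf)
  check_scalar_in(confound_strength, "confound_strength", 0, Inf)
  for (cp in coupled_pairs) {
    if (!all(c("geno", "eeg", "r") %in% names(cp)))
      stop_field("coupled_pairs", "each pair needs `geno`, `eeg`, `r`")
    if (abs(cp$r) > 1) stop_field("coupled_pairs", "|designed r| must be <= 1")
    if (cp$geno < 1 || cp$geno > k_geno || cp$eeg < 1 || cp$eeg > k_eeg)
      stop_field("coupled_pairs", "component index out of range")
  }
  if (!is.null(group_shift)) {
    for (side in c("geno", "eeg")) {
      gs <- group_shift[[side]]
      if (!is.null(gs) && (!is.matrix(gs) || ncol(gs) != 3L ||
                           nrow(gs) != (if (side == "geno") k_geno else k_eeg)))
        stop_field("group_shift", sprintf("`%s` must be a k x 3 matrix", side))
    }
  }
  structure(list(
    n_per_group = n_per_group, n_snps = n_snps, n_features = n_features,
    k_geno = k_geno, k_eeg = k_eeg, coupled_pairs = coupled_pairs,
    group_shift = group_shift, maf_range = maf_range, fst = fst,
    subpop_fractions = subpop_fractions, snp_effect_size = snp_effect_size,
    noise_sd = noise_sd, missing_rate = missing_rate,
    geno_sparsity = geno_sparsity, eeg_sparsity = eeg_sparsity,
    n_ld_duplicate_pairs = as.integer(n_ld_duplicate_pairs),
    n_duplicate_subjects = as.integer(n_duplicate_subjects),
    confound_strength = confound_strength,
    seed = check_count(seed, "seed", min = 0L)), class = "cohort_config")
}

#' Draw cross-correlated latent subject loadings for the two modalities
#'
#' Each modality's loadings start as independent standard normals; each
#' coupled pair is redrawn from a bivariate normal with the designed
#' correlation. Columns are standardized (zero mean, unit sd) before any
#' group shifts are added, so `group_shift` is in within-cohort sd units.
#'
#' @param n subject count.
#' @param config a `cohort_config` (its `k_geno`, `k_eeg`, `coupled_pairs`,
#'   `group_shift` fields are used).
#' @param group_idx integer vector in 1..3 assigning subjects to groups.
#' @param seed RNG seed.
#' @return list with `geno_loadings` (n x k_geno) and `eeg_loadings`
#'   (n x k_eeg).
#' @export
simulate_coupled_loadings <- function(n, config, group_idx, seed = 1L) {
  k_g <- config$k_geno; k_e <- config$k_eeg
  with_seed(seed, {
    G <- matrix(stats::rnorm(n * k_g), n, k_g)
    E <- matrix(stats::rnorm(n * k_e), n, k_e)
    for (cp in config$coupled_pairs) {
      r <- cp$r
      E[, cp$eeg] <- r * G[, cp$geno] + sqrt(1 - r^2) * stats::rnorm(n)
    }
    G <- zstd_cols(G); E <- zstd_cols(E)
    gs <- config$group_shift
    if (!is.null(gs$geno)) G <- G + t(gs$geno[, group_idx, drop = FALSE])
    if (!is.null(gs$eeg)) E <- E + t(gs$eeg[, group_idx, drop = FALSE])
    list(geno_loadings = G, eeg_loadings = E)
  })
}

#' Simulate additive SNP dosages under (sub)population HWE
#'
#' Genotypes are binomial(2, p) draws per subject and SNP. With `fst > 0`
#' each subpopulation receives its own allele frequency from the
#' Balding-Nichols beta distribution around the ancestral MAF. Latent
#' genetic effects enter on the logit scale: the per-subject success
#' probability is `plogis(qlogis(p) + effect_size * map_weight * loading)`,
#' which keeps dosages legal in {0, 1, 2}. Missing entries are injected
#' completely at random.
#'
#' @param maf vector of per-SNP ancestral minor-allele frequencies in
#'   (0, 0.5].
#' @param n_subjects subject count.
#' @param fst fixation index (0 = panmictic).
#' @param subpop_idx integer vector (1 or 2) per subject; required when
#'   `fst > 0`.
#' @param effect_logit optional n_subjects x n_snps matrix of logit-scale
#'   shifts (e.g. `effect_size * loadings %*% maps`).
#' @param missing_rate missingness probability.
#' @param seed RNG seed.
#' @return integer matrix n_subjects x n_snps with NA for missing.
#' @export
simulate_genotypes <- function(maf, n_subjects, fst = 0, subpop_idx = NULL,
                               effect_logit = NULL, missing_rate = 0,
                               seed = 1L) {
  if (any(maf <= 0 | maf > 0.5))
    stop_field("maf", "all values must lie in (0, 0.5]")
  if (fst < 0) stop_field("fst", "must be >= 0")
  m <- length(maf)
  with_seed(seed, {
    P <- matrix(rep(maf, each = n_subjects), n_subjects, m)
    if (fst > 0) {
      if (is.null(subpop_idx)) stop_field("subpop_idx", "required when fst > 0")
      a <- maf * (1 - fst) / fst
      b <- (1 - maf) * (1 - fst) / fst
      p1 <- stats::rbeta(m, a, b)
      p2 <- stats::rbeta(m, a, b)
      P <- rbind(p1, p2)[subpop_idx, , drop = FALSE]
    }
    if (!is.null(effect_logit))
      P <- stats::plogis(stats::qlogis(pmin(pmax(P, 1e-6), 1 - 1e-6)) +
                           effect_logit)
    G <- matrix(stats::rbinom(n_subjects * m, 2L, P), n_subjects, m)
    if (missing_rate > 0)
      G[stats::runif(n_subjects * m) < missing_rate] <- NA_integer_
    G
  })
}

# Sparse super-Gaussian source maps with (near-)disjoint supports. Rows are
# rescaled to equal power (RMS `scale` per support entry) so latent
# components carry comparable signal variance.
sparse_maps <- function(k, p, sparsity, scale = 3) {
  supp_size <- max(3L, round(sparsity * p))
  S <- matrix(0, k, p)
  pool <- sample.int(p)
  pos <- 0L
  for (j in seq_len(k)) {
    if (pos + supp_size <= p) {
      idx <- pool[(pos + 1L):(pos + supp_size)]
      pos <- pos + supp_size
    } else idx <- sample.int(p, supp_size)
    w <- stats::rexp(supp_size) * sample(c(-1, 1), supp_size, replace = TRUE)
    S[j, idx] <- scale * w / sqrt(mean(w^2))
  }
  S
}

cohort_demographics <- function(group_idx) {
  # group order: control, case1 (schizophrenia-like), case2 (psychotic
  # bipolar-like); distributions chosen as typical multisite cohort values
  age_mu <- c(37.07, 31.20, 34.29); age_sd <- c(11.28, 11.08, 12.05)
  male_p <- c(22 / 56, 79 / 105, 60 / 145)
  site_counts <- rbind(
    control = c(11, 3, 1, 0, 11, 30),
    case1   = c(36, 5, 8, 1, 13, 42),
    case2   = c(41, 3, 31, 5, 10, 55))
  sites <- c("Baltimore", "Boston", "Chicago", "Dallas", "Detroit", "Hartford")
  cauc_p <- c(30 / 56, 57 / 105, 95 / 145)
  n <- length(group_idx)
  age <- stats::rnorm(n, age_mu[group_idx], age_sd[group_idx])
  sex <- ifelse(stats::runif(n) < male_p[group_idx], "male", "female")
  site <- vapply(group_idx, function(g)
    sample(sites, 1L, prob = site_counts[g, ]), character(1L))
  ethnicity <- ifelse(stats::runif(n) < cauc_p[group_idx],
                      "Caucasian", "African-American")
  # clinical scores for probands only (controls get NA)
  clin <- function(mu, sd_, lo, hi = Inf) {
    x <- pmin(hi, pmax(lo, stats::rnorm(n, c(0, mu)[group_idx],
                                        c(1, sd_)[group_idx])))
    x[group_idx == 1L] <- NA
    x
  }
  panss_pos <- clin(c(15.09, 14.04), c(5.28, 5.56), 7)
  panss_neg <- clin(c(16.21, 12.84), c(5.73, 4.68), 7)
  panss_gen <- clin(c(30.43, 29.41), c(8.73, 8.51), 16)
  sbs <- clin(c(7.52, 2.09), c(1.34, 1.73), 0, 9)
  cpz <- clin(c(542.01, 383.31), c(410.71, 339.3), 0)
  data.frame(age = age, sex = sex, site = site, ethnicity = ethnicity,
             panss_pos = panss_pos, panss_neg = panss_neg,
             panss_gen = panss_gen, sbs = sbs, cpz = cpz,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic coupled genotype/EEG cohort
#'
#' @param config a [cohort_config()].
#' @return list with `genotypes` (a `genotype_table`), `features` (a
#'   `spectral_features` object of subject spatio-spectral weights) and
#'   `truth` (a `truth_bundle` holding the latent loadings, source maps,
#'   designed correlations, subpopulation and group labels).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  n <- sum(config$n_per_group)
  group_idx <- rep(1:3, config$n_per_group)
  groups <- c("control", "case1", "case2")[group_idx]
  seeds <- fan_seeds(config$seed, 8L)

  subpop_idx <- NULL
  if (config$fst > 0)
    subpop_idx <- with_seed(seeds[1L],
      sample(1:2, n, replace = TRUE, prob = config$subpop_fractions))

  lds <- simulate_coupled_loadings(n, config, group_idx, seed = seeds[2L])

  meta <- with_seed(seeds[3L], cohort_demographics(group_idx))
  if (config$confound_strength > 0) {
    conf <- config$confound_strength *
      (scale(meta$age)[, 1L] + (meta$sex == "male") - 0.5)
    lds$geno_loadings <- zstd_cols(lds$geno_loadings + conf)
    lds$eeg_loadings <- zstd_cols(lds$eeg_loadings + conf)
  }
  if (config$fst > 0) meta$ethnicity <- paste0("pop", subpop_idx)

  maps <- with_seed(seeds[4L], {
    list(geno = sparse_maps(config$k_geno, config$n_snps,
                            config$geno_sparsity, scale = 1),
         eeg = sparse_maps(config$k_eeg, config$n_features,
                           config$eeg_sparsity, scale = 3))
  })

  maf <- with_seed(seeds[5L],
                   stats::runif(config$n_snps, config$maf_range[1L],
                                config$maf_range[2L]))
  effect <- config$snp_effect_size * (lds$geno_loadings %*% maps$geno)
  G <- simulate_genotypes(maf, n, fst = config$fst, subpop_idx = subpop_idx,
                          effect_logit = effect,
                          missing_rate = config$missing_rate,
                          seed = seeds[6L])

  feats <- lds$eeg_loadings %*% maps$eeg +
    with_seed(seeds[7L],
              matrix(stats::rnorm(n * config$n_features,
                                  sd = config$noise_sd),
                     n, config$n_features))

  # optional injections for QC tests
  extra <- with_seed(seeds[8L], {
    out <- list()
    if (config$n_ld_duplicate_pairs > 0) {
      src <- sample.int(config$n_snps - 1L, config$n_ld_duplicate_pairs)
      out$ld_pairs <- cbind(src, src + 1L)
    }
    if (config$n_duplicate_subjects > 0) {
      picks <- sample.int(n, 2L * config$n_duplicate_subjects)
      out$dup_subjects <- matrix(picks, ncol = 2L)
    }
    out
  })
  snp_pos <- snp_positions(config$n_snps, seeds[8L])
  if (!is.null(extra$ld_pairs)) {
    for (q in seq_len(nrow(extra$ld_pairs))) {
      a <- extra$ld_pairs[q, 1L]; b <- extra$ld_pairs[q, 2L]
      G[, b] <- G[, a]
      snp_pos$chromosome[b] <- snp_pos$chromosome[a]
      snp_pos$position[b] <- snp_pos$position[a] + 100L
    }
    ord <- order(snp_pos$chromosome, snp_pos$position)
    # keep SNP order sorted by position after the duplicate placement
    G <- G[, ord, drop = FALSE]
    maps$geno <- maps$geno[, ord, drop = FALSE]
    maf <- maf[ord]
    snp_pos <- snp_pos[ord, ]
  }
  if (!is.null(extra$dup_subjects)) {
    for (q in seq_len(nrow(extra$dup_subjects)))
      G[extra$dup_subjects[q, 2L], ] <- G[extra$dup_subjects[q, 1L], ]
  }

  alleles <- with_seed(seeds[5L] + 1L, t(replicate(config$n_snps,
    sample(c("A", "C", "G", "T"), 2L))))
  snps <- data.frame(
    id = sprintf("snp%06d", seq_len(config$n_snps)),
    chromosome = snp_pos$chromosome, position = snp_pos$position,
    allele_a = alleles[, 1L], allele_b = alleles[, 2L],
    maf_true = maf, stringsAsFactors = FALSE)
  subjects <- cbind(data.frame(id = sprintf("subj%04d", seq_len(n)),
                               group = groups, stringsAsFactors = FALSE),
                    meta)
  rownames(G) <- subjects$id; colnames(G) <- snps$id
  rownames(feats) <- subjects$id
  colnames(feats) <- sprintf("feat%04d", seq_len(config$n_features))

  geno_tab <- genotype_table(G, snps, subjects)
  features <- spectral_features(feats,
                                channel_labels = colnames(feats),
                                n_freq_components = 1L,
                                provenance = "synthetic")
  truth <- structure(list(
    geno_loadings = lds$geno_loadings, eeg_loadings = lds$eeg_loadings,
    geno_maps = maps$geno, eeg_maps = maps$eeg,
    designed_r = if (length(config$coupled_pairs))
      do.call(rbind, lapply(config$coupled_pairs, as.data.frame)) else
        data.frame(geno = integer(), eeg = integer(), r = numeric()),
    subpop_labels = subpop_idx, group_labels = groups,
    config = config), class = "truth_bundle")
  list(genotypes = geno_tab, features = features, truth = truth)
}

snp_positions <- function(n_snps, seed) {
  with_seed(seed + 7L, {
    chrom <- sort(sample(1:22, n_snps, replace = TRUE))
    pos <- integer(n_snps)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(2.4e8, length(idx)))
    }
    data.frame(chromosome = chrom, position = pos)
  })
}
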