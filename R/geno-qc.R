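# SNP-side quality control ---------------------------------------------------

#' Additive minor-allele coding of genotype calls
#'
#' Converts two-allele genotype calls (e.g. `"AG"`) to the count of the
#' minor (B) allele: AA = 0, AB = 1, BB = 2.
#'
#' @param calls character vector of two-character calls, or a missing code.
#' @param allele_a,allele_b the SNP's major and minor allele letters.
#' @param missing_codes calls treated as missing (returned as NA).
#' @return integer vector of dosages with NA for missing calls.
#' @export
code_additive <- function(calls, allele_a, allele_b,
                          missing_codes = c("00", "--", "NN", "")) {
  out <- rep(NA_integer_, length(calls))
  miss <- is.na(calls) | calls %in% missing_codes
  chk <- calls[!miss]
  a1 <- substr(chk, 1L, 1L); a2 <- substr(chk, 2L, 2L)
  bad <- !(a1 %in% c(allele_a, allele_b)) | !(a2 %in% c(allele_a, allele_b))
  if (any(bad))
    stop(sprintf("allele not in {%s, %s}: %s", allele_a, allele_b,
                 paste(unique(chk[bad]), collapse = ", ")), call. = FALSE)
  out[!miss] <- (a1 == allele_b) + (a2 == allele_b)
  out
}

# QC report plumbing ----------------------------------------------------------

qc_entry <- function(name, threshold, removed, remaining, detail = NULL) {
  list(name = name, threshold = threshold, removed = removed,
       remaining = remaining, detail = detail)
}

qc_entries_df <- function(entries) {
  do.call(rbind, lapply(entries, function(e)
    data.frame(step = e$name, threshold = as.character(e$threshold),
               removed = e$removed, remaining = e$remaining,
               stringsAsFactors = FALSE)))
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact P-value from the Levene-Haldane conditional distribution
#' of the heterozygote count given the allele counts: the sum of the
#' probabilities of all heterozygote configurations no more likely than the
#' observed one. Computed with the numerically stable ratio recurrence.
#'
#' @param n_aa,n_ab,n_bb genotype counts (AA, AB, BB).
#' @return P-value in (0, 1]; monomorphic samples return 1.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0",
                                         call. = FALSE)
  n <- n_aa + n_ab + n_bb
  if (n < 1L) stop("at least one genotype required", call. = FALSE)
  nb <- 2L * n_bb + n_ab                 # minor-ish allele count
  rare <- min(nb, 2L * n - nb)
  if (rare == 0L) return(1)
  # heterozygote counts share the parity of the rare allele count
  het_vals <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(het_vals))
  # start from mid-range het and recur outward via probability ratios
  mid_i <- which.min(abs(het_vals - rare * (2 * n - rare) / (2 * n)))
  probs[mid_i] <- 1
  # P(het+2)/P(het) = 4 * n_homr * n_homc / ((het+2) * (het+1))
  homr <- function(het) (rare - het) / 2          # rare homozygotes
  homc <- function(het) n - het - (rare - het) / 2
  if (mid_i < length(het_vals)) for (i in mid_i:(length(het_vals) - 1L)) {
    het <- het_vals[i]
    probs[i + 1L] <- probs[i] * 4 * homr(het) * homc(het) /
      ((het + 2) * (het + 1))
  }
  if (mid_i > 1L) for (i in mid_i:2L) {
    het <- het_vals[i]
    probs[i - 1L] <- probs[i] * het * (het - 1) /
      (4 * (homr(het) + 1) * (homc(het) + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, het_vals)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Sample-level genotype quality control
#'
#' Removes subjects with (i) missing rate above `missing_max`, (ii)
#' heterozygosity further than `het_sd` standard deviations from the cohort
#' mean, and (iii) one member (the one with the higher missing rate) of any
#' pair whose method-of-moments relatedness exceeds `ibd_max`. Relatedness
#' is the allele-frequency-standardized genetic covariance (GRM
#' off-diagonal), approximately 1 for duplicates/identical twins, 0.5 for
#' first-degree relatives and 0 for unrelated pairs.
#'
#' @param gt a `genotype_table`.
#' @param missing_max per-subject missing-rate ceiling.
#' @param het_sd heterozygosity z-score cutoff.
#' @param ibd_max relatedness ceiling.
#' @return list with the filtered `genotype_table` (`table`), `entries`
#'   (QC-report steps) and per-subject `stats`.
#' @export
sample_qc <- function(gt, missing_max = 0.03, het_sd = 3, ibd_max = 0.1875) {
  stopifnot(inherits(gt, "genotype_table"))
  if (nrow(gt$dosage) < 2L) stop("need at least 2 subjects", call. = FALSE)
  X <- gt$dosage
  n0 <- nrow(X)
  miss_rate <- rowMeans(is.na(X))
  keep <- miss_rate <= missing_max
  e1 <- qc_entry("subject_missing_rate", missing_max, sum(!keep), sum(keep))

  het <- rowMeans(X[, , drop = FALSE] == 1L, na.rm = TRUE)
  hz <- (het - mean(het[keep])) / stats::sd(het[keep])
  keep2 <- keep & abs(hz) <= het_sd
  e2 <- qc_entry("subject_heterozygosity", paste0(het_sd, " sd"),
                 sum(keep) - sum(keep2), sum(keep2))

  idx <- which(keep2)
  Xs <- X[idx, , drop = FALSE]
  p <- colMeans(Xs, na.rm = TRUE) / 2
  ok <- p > 0.01 & p < 0.99 & !is.na(p)
  Z <- sweep(Xs[, ok, drop = FALSE], 2L, 2 * p[ok], "-")
  Z <- sweep(Z, 2L, sqrt(2 * p[ok] * (1 - p[ok])), "/")
  Z[is.na(Z)] <- 0
  m_eff <- tcrossprod(!is.na(Xs[, ok, drop = FALSE]) * 1)
  K <- tcrossprod(Z) / pmax(m_eff, 1L)
  rel_drop <- logical(length(idx))
  pairs <- which(upper.tri(K) & K > ibd_max, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (q in order(-K[pairs])) {
      i <- pairs[q, 1L]; j <- pairs[q, 2L]
      if (rel_drop[i] || rel_drop[j]) next
      drop_j <- miss_rate[idx[j]] >= miss_rate[idx[i]]
      rel_drop[if (drop_j) j else i] <- TRUE
    }
  }
  keep3 <- keep2
  keep3[idx[rel_drop]] <- FALSE
  e3 <- qc_entry("subject_relatedness", ibd_max, sum(rel_drop), sum(keep3))

  stats_df <- data.frame(id = gt$subjects$id, missing_rate = miss_rate,
                         het_fraction = het, het_z = hz,
                         max_relatedness = NA_real_,
                         stringsAsFactors = FALSE)
  diag(K) <- NA
  stats_df$max_relatedness[idx] <- apply(K, 1L, max, na.rm = TRUE)
  list(table = genotype_table(X[keep3, , drop = FALSE], gt$snps,
                              gt$subjects[keep3, , drop = FALSE]),
       entries = list(e1, e2, e3), stats = stats_df)
}

#' SNP-level filters
#'
#' Removes SNPs failing any of: non-autosomal location (optional), minor
#' allele frequency below `maf_min`, call rate below `call_min`,
#' Hardy-Weinberg exact-test P below `hwe_alpha` in control subjects, or
#' differential missingness between cases and controls (Fisher exact test
#' on called/missing counts) below `diffmiss_alpha`.
#'
#' @param gt a `genotype_table` (after [sample_qc()] in the standard order).
#' @param maf_min,call_min,hwe_alpha,diffmiss_alpha thresholds.
#' @param autosomes_only drop chromosomes outside 1..22 first.
#' @return list with the filtered `table`, QC `entries` and per-SNP `stats`
#'   (MAF, call rate, HWE P, differential-missingness P).
#' @export
snp_filters <- function(gt, maf_min = 0.05, call_min = 0.98,
                        hwe_alpha = 1e-5, diffmiss_alpha = 1e-5,
                        autosomes_only = TRUE) {
  stopifnot(inherits(gt, "genotype_table"))
  X <- gt$dosage
  is_control <- gt$subjects$group == "control"
  if (!any(is_control)) stop("no control subjects for the HWE filter",
                             call. = FALSE)
  m0 <- ncol(X)
  keep <- rep(TRUE, m0)
  entries <- list()
  if (autosomes_only) {
    keep <- gt$snps$chromosome %in% 1:22
    entries <- c(entries, list(qc_entry("autosomes_only", "chr 1-22",
                                        sum(!keep), sum(keep))))
  }
  call_rate <- colMeans(!is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  k2 <- keep & maf >= maf_min & !is.na(maf)
  entries <- c(entries, list(qc_entry("maf", maf_min, sum(keep) - sum(k2),
                                      sum(k2))))
  k3 <- k2 & call_rate >= call_min
  entries <- c(entries, list(qc_entry("call_rate", call_min,
                                      sum(k2) - sum(k3), sum(k3))))
  Xc <- X[is_control, , drop = FALSE]
  hwe_p <- vapply(seq_len(m0), function(j) {
    if (!k3[j]) return(NA_real_)
    g <- Xc[, j]; g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1L))
  k4 <- k3 & (is.na(hwe_p) | hwe_p >= hwe_alpha)
  entries <- c(entries, list(qc_entry("hwe_controls", hwe_alpha,
                                      sum(k3) - sum(k4), sum(k4))))
  case <- !is_control
  dm_p <- vapply(seq_len(m0), function(j) {
    if (!k4[j]) return(NA_real_)
    called <- !is.na(X[, j])
    tab <- table(factor(called, c(FALSE, TRUE)),
                 factor(case, c(FALSE, TRUE)))
    if (any(rowSums(tab) == 0L)) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1L))
  k5 <- k4 & (is.na(dm_p) | dm_p >= diffmiss_alpha)
  entries <- c(entries, list(qc_entry("differential_missingness",
                                      diffmiss_alpha, sum(k4) - sum(k5),
                                      sum(k5))))
  stats_df <- data.frame(id = gt$snps$id, maf = maf, call_rate = call_rate,
                         hwe_p = hwe_p, diffmiss_p = dm_p,
                         stringsAsFactors = FALSE)
  list(table = genotype_table(X[, k5, drop = FALSE],
                              gt$snps[k5, , drop = FALSE], gt$subjects),
       entries = entries, stats = stats_df)
}

#' Window-based LD pruning
#'
#' Greedy left-to-right scan within each chromosome: for every retained SNP,
#' any later SNP within `window_bp` base pairs whose squared dosage
#' correlation exceeds `r2_max` is dropped (at equal position the SNP with
#' the lower MAF is dropped). After pruning no retained pair within a
#' window exceeds `r2_max`.
#'
#' @param gt a `genotype_table`.
#' @param r2_max squared-correlation ceiling.
#' @param window_bp window size in base pairs (closed interval).
#' @return list with the pruned `table` and QC `entries`.
#' @export
ld_prune <- function(gt, r2_max = 0.8, window_bp = 10000) {
  stopifnot(inherits(gt, "genotype_table"))
  ord <- order(gt$snps$chromosome, gt$snps$position)
  if (is.unsorted(ord)) {
    warning("SNPs were not position-sorted; sorting internally",
            call. = FALSE)
    gt <- genotype_table(gt$dosage[, ord, drop = FALSE],
                         gt$snps[ord, , drop = FALSE], gt$subjects)
  }
  X <- gt$dosage
  m <- ncol(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  chrom <- gt$snps$chromosome; pos <- gt$snps$position
  keep <- rep(TRUE, m)
  for (j in seq_len(m)) {
    if (!keep[j]) next
    j2 <- j + 1L
    while (j2 <= m && chrom[j2] == chrom[j] &&
           pos[j2] - pos[j] <= window_bp) {
      if (keep[j2]) {
        r <- suppressWarnings(
          stats::cor(X[, j], X[, j2], use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_max) {
          if (pos[j2] == pos[j] && maf[j2] > maf[j]) {
            keep[j] <- FALSE
            break
          } else keep[j2] <- FALSE
        }
      }
      j2 <- j2 + 1L
    }
  }
  entry <- qc_entry("ld_prune", sprintf("r2 > %g in %d bp", r2_max,
                                        window_bp),
                    sum(!keep), sum(keep))
  list(table = genotype_table(X[, keep, drop = FALSE],
                              gt$snps[keep, , drop = FALSE], gt$subjects),
       entries = list(entry))
}

#' Eigenstrat-style population-stratification adjustment
#'
#' PCA on the standardized (mean-imputed) dosage matrix; each of the top
#' `n_components_scan` subject-score vectors is tested against self-reported
#' ethnicity by one-way ANOVA, and every component with P below
#' `assoc_alpha` is regressed out of all SNP dosage vectors
#' (residualization, intercept included). The report also records whether
#' any adjusted component differs between cases and controls.
#'
#' @param gt a `genotype_table` with an `ethnicity` subject column.
#' @param n_components_scan number of leading components examined.
#' @param assoc_alpha ANOVA significance level for flagging a component.
#' @return list: `adjusted` (subjects x SNPs numeric matrix, residualized),
#'   `scores` (subject PC scores), `flagged` (indices of adjusted
#'   components), `ethnicity_p`, `case_control_p` and QC `entries`.
#' @export
stratification_adjust <- function(gt, n_components_scan = 10,
                                  assoc_alpha = 0.05) {
  stopifnot(inherits(gt, "genotype_table"))
  eth <- gt$subjects$ethnicity
  if (is.null(eth)) stop("ethnicity labels required", call. = FALSE)
  X <- gt$dosage * 1.0
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  Z <- zstd_cols(X)
  n_pc <- min(n_components_scan, nrow(Z) - 1L, ncol(Z))
  sv <- svd(Z, nu = n_pc, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pc)], n_pc)
  if (length(unique(eth)) < 2L) {
    entry <- qc_entry("stratification_adjust", assoc_alpha, 0, ncol(X),
                      detail = "single ethnicity category; nothing adjustable")
    return(list(adjusted = X, scores = scores, flagged = integer(),
                ethnicity_p = rep(NA_real_, n_pc),
                case_control_p = rep(NA_real_, n_pc),
                entries = list(entry)))
  }
  eth_f <- factor(eth)
  eth_p <- vapply(seq_len(n_pc), function(j)
    stats::anova(stats::lm(scores[, j] ~ eth_f))$`Pr(>F)`[1L], numeric(1L))
  flagged <- which(eth_p < assoc_alpha)
  adjusted <- X
  if (length(flagged)) {
    D <- cbind(1, scores[, flagged, drop = FALSE])
    adjusted <- X - D %*% qr.coef(qr(D), X)
  }
  is_case <- factor(gt$subjects$group != "control")
  cc_p <- vapply(seq_len(n_pc), function(j)
    stats::anova(stats::lm(scores[, j] ~ is_case))$`Pr(>F)`[1L],
    numeric(1L))
  entry <- qc_entry("stratification_adjust", assoc_alpha,
                    removed = 0, remaining = ncol(X),
                    detail = sprintf("adjusted components: %s",
                                     if (length(flagged))
                                       paste(flagged, collapse = ",") else
                                         "none"))
  list(adjusted = adjusted, scores = scores, flagged = flagged,
       ethnicity_p = eth_p, case_control_p = cc_p, entries = list(entry))
}

# Logistic Wald test of case status on one dosage vector; falls back to the
# score test under (quasi-)separation.
logistic_snp_test <- function(x, y) {
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0) return(c(p = 1, beta = 0, flagged = 0))
  D <- cbind(1, x)
  fit <- suppressWarnings(stats::glm.fit(D, y,
                                         family = stats::binomial()))
  beta <- fit$coefficients[2L]
  sep <- !fit$converged || any(abs(fit$coefficients) > 15)
  if (!sep) {
    Wm <- fit$weights
    XtWX <- crossprod(D * Wm, D)
    se <- sqrt(diag(solve(XtWX)))[2L]
    z <- beta / se
    return(c(p = 2 * stats::pnorm(-abs(z)), beta = beta, flagged = 0))
  }
  # score test at beta = 0
  yb <- mean(y)
  U <- sum(x * (y - yb))
  V <- yb * (1 - yb) * sum((x - mean(x))^2)
  stat <- if (V > 0) U^2 / V else 0
  c(p = stats::pchisq(stat, 1L, lower.tail = FALSE), beta = beta,
    flagged = 1)
}

#' Univariate case-control prefilter
#'
#' Per SNP and per case group, logistic regression of case status on the
#' (stratification-adjusted) dosage; the selected set is the union over
#' contrasts of SNPs with Wald P below `alpha`. Perfectly separating SNPs
#' fall back to the score test and are flagged. A q-q table (empirical vs
#' theoretical -log10 P) and the genomic-inflation factor lambda_GC are
#' returned per contrast.
#'
#' @param adjusted numeric matrix subjects x SNPs (residualized dosages
#'   from [stratification_adjust()], or raw dosages).
#' @param groups subject group labels (`control`, `case1`, `case2`).
#' @param snp_ids SNP identifiers (defaults to column names).
#' @param alpha per-contrast uncorrected selection threshold.
#' @return list: `selected` (SNP ids in the merged set), `stats` (per SNP
#'   and contrast: P, beta, separation flag), `lambda_gc` per contrast and
#'   `qq` (per-contrast q-q table).
#' @export
univariate_prefilter <- function(adjusted, groups, snp_ids = NULL,
                                 alpha = 0.025) {
  if (is.null(snp_ids)) snp_ids <- colnames(adjusted)
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(ncol(adjusted)))
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need at least two groups",
                                        call. = FALSE)
  contrasts <- intersect(c("case1", "case2"), unique(groups))
  m <- ncol(adjusted)
  res <- list(); lambda <- c(); qq <- list()
  for (cg in contrasts) {
    sel <- groups %in% c("control", cg)
    y <- as.integer(groups[sel] == cg)
    stats_m <- t(vapply(seq_len(m), function(j)
      logistic_snp_test(adjusted[sel, j], y), numeric(3L)))
    pvals <- stats_m[, 1L]
    chisq <- stats::qchisq(pmax(pvals, 1e-300), 1L, lower.tail = FALSE)
    lambda[cg] <- stats::median(chisq) / stats::qchisq(0.5, 1L)
    o <- sort(pvals)
    qq[[cg]] <- data.frame(
      theoretical = -log10(stats::ppoints(length(o))),
      observed = -log10(o))
    res[[cg]] <- data.frame(id = snp_ids, contrast = cg, p = pvals,
                            beta = stats_m[, 2L],
                            separation = stats_m[, 3L] == 1,
                            stringsAsFactors = FALSE)
  }
  all_stats <- do.call(rbind, res)
  selected <- unique(unlist(lapply(res, function(d) d$id[d$p < alpha])))
  list(selected = selected, stats = all_stats, lambda_gc = lambda, qq = qq,
       alpha = alpha)
}
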