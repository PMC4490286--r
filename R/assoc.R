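# Component-pair association testing -----------------------------------------

# Build a full-rank covariate design from a subject metadata frame:
# age linear, sex/ethnicity/site as indicator contrasts. Aliased columns
# are dropped with a warning.
covariate_design <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    return(NULL)
  covariates <- as.data.frame(covariates)
  keep <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) > 1L,
                 logical(1L))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0L) return(NULL)
  D <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  q <- qr(cbind(1, D))
  if (q$rank < ncol(D) + 1L) {
    warning("rank-deficient covariate design; dropping aliased columns",
            call. = FALSE)
    ind <- q$pivot[seq_len(q$rank)]
    ind <- setdiff(ind, 1L) - 1L
    D <- D[, ind, drop = FALSE]
  }
  D
}

#' Partial (covariate-adjusted) association of all component pairs
#'
#' For every (EEG component, SNP component) pair, computes the raw Pearson
#' correlation of the loading-coefficient columns and the partial
#' correlation given the covariates (both columns residualized on the
#' covariate design, residuals correlated). Two-sided P-values come from
#' the t distribution with n - 2 - q degrees of freedom (q = covariate
#' columns; q = 0 for the raw correlation). Significance is flagged at the
#' Bonferroni threshold `alpha / (k_eeg * k_snp)`.
#'
#' @param eeg_lc,snp_lc loading matrices, subjects x k (same subjects).
#' @param covariates data frame of subject covariates (e.g. age, sex,
#'   ethnicity, site), or NULL for no adjustment.
#' @param alpha family-wise level before Bonferroni division.
#' @return an `association_table` data frame: one row per pair with
#'   `eeg_comp`, `snp_comp`, `r_raw`, `p_raw`, `r_partial`, `p_partial`,
#'   `significant` (partial P below the corrected threshold); attributes
#'   `threshold`, `n_pairs`, `covariates`.
#' @export
partial_association_matrix <- function(eeg_lc, snp_lc, covariates = NULL,
                                       alpha = 0.05) {
  if (nrow(eeg_lc) != nrow(snp_lc))
    stop("loading matrices must have equal subject counts", call. = FALSE)
  n <- nrow(eeg_lc)
  D <- covariate_design(covariates)
  q <- if (is.null(D)) 0L else ncol(D)
  resid_on <- function(M) {
    if (is.null(D)) return(scale(M, scale = FALSE))
    Dm <- cbind(1, D)
    M - Dm %*% qr.coef(qr(Dm), M)
  }
  r_raw <- colcor(eeg_lc, snp_lc)
  r_par <- if (is.null(D)) r_raw else
    colcor(resid_on(eeg_lc), resid_on(snp_lc))
  thr <- bonferroni_threshold(alpha, ncol(eeg_lc), ncol(snp_lc))
  p_of <- function(r, df) {
    t <- abs(r) * sqrt(df / pmax(1 - r^2, 1e-300))
    2 * stats::pt(t, df, lower.tail = FALSE)
  }
  p_raw <- p_of(r_raw, n - 2)
  p_par <- p_of(r_par, n - 2 - q)
  grid <- expand.grid(eeg_comp = seq_len(ncol(eeg_lc)),
                      snp_comp = seq_len(ncol(snp_lc)))
  out <- data.frame(grid,
                    r_raw = r_raw[as.matrix(grid)],
                    p_raw = p_raw[as.matrix(grid)],
                    r_partial = r_par[as.matrix(grid)],
                    p_partial = p_par[as.matrix(grid)])
  out$significant <- out$p_partial < thr$threshold
  structure(out, threshold = thr$threshold, n_pairs = thr$n_pairs,
            covariates = if (is.null(D)) character() else colnames(D),
            class = c("association_table", "data.frame"))
}

#' Bonferroni threshold over all component pairs
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param k_eeg,k_snp component counts of the two modalities.
#' @return list with `threshold` (`alpha / (k_eeg * k_snp)`) and `n_pairs`.
#' @export
bonferroni_threshold <- function(alpha, k_eeg, k_snp) {
  check_scalar_in(alpha, "alpha", 0, 1, TRUE, TRUE)
  k_eeg <- check_count(k_eeg, "k_eeg"); k_snp <- check_count(k_snp, "k_snp")
  list(threshold = alpha / (k_eeg * k_snp), n_pairs = k_eeg * k_snp)
}

#' Group differences and clinical correlations of loading coefficients
#'
#' For each loading column: pairwise group comparisons (control vs each
#' case group and case1 vs case2) using a two-sided t-test when both groups
#' pass a Shapiro-Wilk normality check at 0.05, otherwise a Mann-Whitney
#' rank-sum test (flagged); plus Pearson correlation with each clinical
#' score over subjects with non-missing scores. Comparisons with fewer than
#' 3 subjects per group are skipped with a warning.
#'
#' @param lc loading matrix, subjects x k (column names used in the report).
#' @param groups subject group labels.
#' @param clinical optional data frame of clinical scores (NA allowed).
#' @return list with data frames `group_tests` (component, comparison,
#'   test used, statistic, P) and `clinical_tests` (component, score, n, r,
#'   P).
#' @export
group_and_clinical_tests <- function(lc, groups, clinical = NULL) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need at least 2 groups",
                                        call. = FALSE)
  if (is.null(colnames(lc))) colnames(lc) <- paste0("comp", seq_len(ncol(lc)))
  pairs <- list(c("control", "case1"), c("control", "case2"),
                c("case1", "case2"))
  pairs <- Filter(function(p) all(p %in% groups), pairs)
  gt_rows <- list()
  for (j in seq_len(ncol(lc))) for (pr in pairs) {
    a <- lc[groups == pr[1L], j]; b <- lc[groups == pr[2L], j]
    if (length(a) < 3L || length(b) < 3L) {
      warning(sprintf("comparison %s vs %s skipped (group < 3 subjects)",
                      pr[1L], pr[2L]), call. = FALSE)
      next
    }
    normal <- tryCatch(
      stats::shapiro.test(a)$p.value >= 0.05 &&
        stats::shapiro.test(b)$p.value >= 0.05,
      error = function(e) FALSE)
    if (normal) {
      tt <- stats::t.test(a, b)
      row <- data.frame(component = colnames(lc)[j],
                        comparison = paste(pr, collapse = " vs "),
                        test = "t", statistic = unname(tt$statistic),
                        p = tt$p.value)
    } else {
      wt <- stats::wilcox.test(a, b, exact = FALSE)
      row <- data.frame(component = colnames(lc)[j],
                        comparison = paste(pr, collapse = " vs "),
                        test = "wilcoxon", statistic = unname(wt$statistic),
                        p = wt$p.value)
    }
    gt_rows[[length(gt_rows) + 1L]] <- row
  }
  cl_rows <- list()
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical)
    for (j in seq_len(ncol(lc))) for (sc in names(clinical)) {
      ok <- !is.na(clinical[[sc]])
      if (sum(ok) < 3L) next
      ct <- stats::cor.test(lc[ok, j], clinical[[sc]][ok])
      cl_rows[[length(cl_rows) + 1L]] <-
        data.frame(component = colnames(lc)[j], score = sc, n = sum(ok),
                   r = unname(ct$estimate), p = ct$p.value)
    }
  }
  list(group_tests = if (length(gt_rows)) do.call(rbind, gt_rows) else NULL,
       clinical_tests = if (length(cl_rows)) do.call(rbind, cl_rows) else
         NULL)
}
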