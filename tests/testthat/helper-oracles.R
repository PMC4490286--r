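# Independent oracles used across the suite. Each is a deliberately naive
# implementation on a different code path from the package functions it
# checks.

# Levene-Haldane HWE probabilities by direct log-gamma enumeration.
hwe_enumeration_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- 2 * n_bb + n_ab
  rare <- min(nb, 2 * n - nb)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    r_hom <- (rare - h) / 2
    c_hom <- n - h - r_hom
    lgamma(n + 1) - lgamma(r_hom + 1) - lgamma(c_hom + 1) - lgamma(h + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[match(n_ab, hets)] * (1 + 1e-10)]))
}

# Naive LD pruning: precompute the full r^2 matrix, then apply the greedy
# left-to-right rule by scanning every pair in every window.
ld_prune_bruteforce <- function(dosage, chrom, pos, r2_max = 0.8,
                                window_bp = 10000) {
  m <- ncol(dosage)
  R2 <- suppressWarnings(stats::cor(dosage,
                                    use = "pairwise.complete.obs"))^2
  p <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)
  for (j in seq_len(m)) {
    if (!keep[j]) next
    for (j2 in seq_len(m)) {
      if (j2 <= j || !keep[j2]) next
      if (chrom[j2] != chrom[j]) next
      if (pos[j2] - pos[j] > window_bp || pos[j2] < pos[j]) next
      if (!is.na(R2[j, j2]) && R2[j, j2] > r2_max) {
        if (pos[j2] == pos[j] && maf[j2] > maf[j]) {
          keep[j] <- FALSE
          break
        } else keep[j2] <- FALSE
      }
    }
  }
  keep
}

# Two-step OLS partial correlation for a single pair of vectors.
partial_cor_ols_oracle <- function(x, y, D) {
  rx <- stats::residuals(stats::lm(x ~ D))
  ry <- stats::residuals(stats::lm(y ~ D))
  stats::cor(rx, ry)
}

# Exhaustive assignment by permutation enumeration (small instances).
assignment_bruteforce <- function(S) {
  permn <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(permn(v[-i]), function(p) c(v[i], p))))
  }
  n <- nrow(S); m <- ncol(S)
  if (n > m) return(assignment_bruteforce(t(S)))
  best <- -Inf
  for (cols in utils::combn(seq_len(m), n, simplify = FALSE))
    for (pp in permn(cols)) {
      tot <- sum(S[cbind(seq_len(n), pp)])
      if (tot > best) best <- tot
    }
  best
}

# Super-Gaussian (Laplace-like) source matrix for ICA recovery tests.
laplace_sources <- function(k, p) {
  matrix(stats::rexp(k * p) * sample(c(-1, 1), k * p, replace = TRUE), k, p)
}

# Small genotype_table fixture with controllable per-SNP generators.
toy_genotype_table <- function(dosage, chrom = NULL, pos = NULL,
                               groups = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(groups)) groups <- rep(c("control", "case1"), length.out = n)
  snps <- data.frame(id = sprintf("s%03d", seq_len(m)), chromosome = chrom,
                     position = pos, allele_a = "A", allele_b = "C",
                     stringsAsFactors = FALSE)
  subjects <- data.frame(id = sprintf("i%03d", seq_len(n)), group = groups,
                         ethnicity = "pop1", stringsAsFactors = FALSE)
  rownames(dosage) <- subjects$id
  colnames(dosage) <- snps$id
  genotype_table(dosage, snps, subjects)
}
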