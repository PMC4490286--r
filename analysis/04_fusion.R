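#!/usr/bin/env Rscript
# Stage 4: model-order selection, parallel ICA and association testing.
#
# Loads the QC'd, prefiltered, standardized dosages and the EEG feature
# weights; picks the EEG order by minimum description length and the SNP
# order by the stability (consistency) criterion; runs the coupled
# two-modality Infomax decomposition; tests every component pair by
# partial correlation given age, sex, ethnicity and site with Bonferroni
# correction over the k_eeg x k_snp grid; scores recovery against the
# generating truth; and compares significant loading coefficients across
# groups.
#
# Outputs under results/: association.tsv, component tables
# (component_*_*.tsv), group_tests.tsv, fusion_state.rds.

suppressMessages(library(paricaeeg))
qc <- readRDS("results/qc_state.rds")
truth <- readRDS("results/data/truth.rds")

snp_mat <- scale(qc$snp_mat)
snp_mat[!is.finite(snp_mat)] <- 0
colnames(snp_mat) <- qc$snp_ids
feats <- as.matrix(read.delim("results/data/features.tsv", row.names = 1,
                              check.names = FALSE))
feats <- feats[match(qc$subjects$id, rownames(feats)), ]

k_eeg <- estimate_order_mdl(feats)
k_snp_stab <- estimate_order_stability(snp_mat, 5:12, n_runs = 10,
                                       seed = 11, max_iter = 300)
k_snp <- as.integer(k_snp_stab)
cat(sprintf("Model order: EEG (MDL) = %d, SNP (stability) = %d\n",
            k_eeg, k_snp))

fit <- para_ica(snp_mat, feats, k_snp = k_snp, k_eeg = k_eeg, seed = 12,
                max_iter = 3000)
cat(sprintf("Parallel ICA %s after %d iterations\n",
            ifelse(fit$converged, "converged", "did NOT converge"),
            fit$iterations))

covars <- qc$subjects[, c("age", "sex", "ethnicity", "site")]
assoc <- partial_association_matrix(fit$eeg$loadings, fit$snp$loadings,
                                    covariates = covars, alpha = 0.05)
write.table(as.data.frame(assoc), "results/association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- assoc[assoc$significant, ]
cat(sprintf("Significant pairs at P < 0.05/%d:\n", attr(assoc, "n_pairs")))
print(sig[, c("eeg_comp", "snp_comp", "r_partial", "p_partial")],
      row.names = FALSE)

# recovery against the generating truth
r_geno <- max(abs(cor(fit$snp$loadings, truth$geno_loadings[
  match(qc$subjects$id, sprintf("subj%04d", seq_len(306))), 1])))
r_eeg <- max(abs(cor(fit$eeg$loadings, truth$eeg_loadings[
  match(qc$subjects$id, sprintf("subj%04d", seq_len(306))), 1])))
cat(sprintf("Truth recovery |r|: coupled genetic comp %.3f, EEG comp %.3f\n",
            r_geno, r_eeg))

snp_tabs <- zscore_select(fit$snp, 2, feature_names = colnames(snp_mat))
eeg_tabs <- zscore_select(fit$eeg, 2, feature_names = colnames(feats))
for (j in seq_along(snp_tabs))
  write.table(snp_tabs[[j]], sprintf("results/component_snp_G%d.tsv", j),
              sep = "\t", quote = FALSE, row.names = FALSE)
for (j in seq_along(eeg_tabs))
  write.table(eeg_tabs[[j]], sprintf("results/component_eeg_E%d.tsv", j),
              sep = "\t", quote = FALSE, row.names = FALSE)
if (nrow(sig)) {
  cat(sprintf("Top pair: E%d has %d features and G%d has %d SNPs at |Z| >= 2\n",
              sig$eeg_comp[1], nrow(eeg_tabs[[sig$eeg_comp[1]]]),
              sig$snp_comp[1], nrow(snp_tabs[[sig$snp_comp[1]]])))
  lc <- cbind(fit$eeg$loadings[, sig$eeg_comp[1], drop = FALSE],
              fit$snp$loadings[, sig$snp_comp[1], drop = FALSE])
  colnames(lc) <- c(sprintf("E%d", sig$eeg_comp[1]),
                    sprintf("G%d", sig$snp_comp[1]))
  clin <- qc$subjects[, c("panss_pos", "panss_neg", "panss_gen", "sbs",
                          "cpz")]
  grp <- group_and_clinical_tests(lc, qc$subjects$group, clinical = clin)
  write.table(grp$group_tests, "results/group_tests.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(grp$clinical_tests, "results/clinical_tests.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("Group differences of the significant loading coefficients:\n")
  print(grp$group_tests, row.names = FALSE)
}
saveRDS(list(fit = fit, snp_mat = snp_mat, feats = feats, assoc = assoc),
        "results/fusion_state.rds")
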