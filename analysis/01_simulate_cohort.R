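#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a three-group cohort (56 controls, 105 + 145 probands) with
# 2000 SNP dosages and 512 EEG spatio-spectral feature weights. Nine sparse
# genetic components and five EEG components underlie the data; one
# (genetic 1, EEG 1) pair of subject loadings is coupled at r = 0.5 and
# shifted in the two proband groups, mimicking a disease-associated
# genotype-phenotype link. Ground truth is kept for later scoring.
#
# Outputs under results/data/: PLINK BED/BIM/FAM + subject metadata,
# feature TSV, truth summary.

suppressMessages(library(paricaeeg))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

shift <- matrix(0, 9, 3); shift[1, 2:3] <- c(0.8, 0.6)
eshift <- matrix(0, 5, 3); eshift[1, 2:3] <- c(0.8, 0.6)
cfg <- cohort_config(
  n_per_group = c(control = 56, case1 = 105, case2 = 145),
  n_snps = 2000, n_features = 512, k_geno = 9, k_eeg = 5,
  coupled_pairs = list(list(geno = 1, eeg = 1, r = 0.5)),
  group_shift = list(geno = shift, eeg = eshift),
  snp_effect_size = 2, noise_sd = 0.3, geno_sparsity = 0.03,
  missing_rate = 0.005, seed = 2026)
ch <- generate_cohort(cfg)

write_plink(ch$genotypes, "results/data/cohort")
write.table(data.frame(id = rownames(ch$features$weights),
                       ch$features$weights, check.names = FALSE),
            "results/data/features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(ch$truth, "results/data/truth.rds")   # scored in later stages

cat(sprintf("Cohort: %d subjects (%s), %d SNPs, %d features\n",
            nrow(ch$genotypes$dosage),
            paste(table(ch$genotypes$subjects$group)[
              c("control", "case1", "case2")], collapse = "/"),
            ncol(ch$genotypes$dosage), ncol(ch$features$weights)))
cat(sprintf("Designed coupling: genetic comp 1 ~ EEG comp 1 at r = 0.5 (empirical truth r = %.3f)\n",
            cor(ch$truth$geno_loadings[, 1], ch$truth$eeg_loadings[, 1])))
cat(sprintf("Genotype missingness: %.2f%%\n",
            100 * mean(is.na(ch$genotypes$dosage))))
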