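Package: paricaeeg
Title: Parallel ICA for Joint SNP and EEG Spectral Component Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multivariate genotype-phenotype association for imaging-genetics
    cohorts: SNP quality control (sample filters, Hardy-Weinberg exact test,
    LD pruning, eigenstrat-style stratification adjustment, univariate
    case-control prefiltering), group ICA compression of EEG amplitude
    spectra, minimum-description-length and stability-based model-order
    selection, a coupled two-modality Infomax ICA (parallel ICA) that
    maximizes cross-modal loading correlation alongside source independence,
    covariate-adjusted association testing with Bonferroni correction over
    component pairs, group and clinical comparisons, and leave-one-out
    component reliability. Includes a synthetic-cohort generator with known
    latent ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
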