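# Core data containers -------------------------------------------------------

#' Construct a genotype table
#'
#' Bundles an additive dosage matrix (subjects x SNPs, values 0/1/2 with NA
#' for missing calls) with SNP and subject metadata.
#'
#' @param dosage integer/numeric matrix, subjects x SNPs.
#' @param snps data frame with at least `id`, `chromosome`, `position`,
#'   `allele_a`, `allele_b` (allele B is the minor allele by convention).
#' @param subjects data frame with at least `id` and `group`
#'   (control/case1/case2); typically also age, sex, site, ethnicity and
#'   clinical scores.
#' @return a `genotype_table`.
#' @export
genotype_table <- function(dosage, snps, subjects) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix", call. = FALSE)
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (nrow(dosage) != nrow(subjects))
    stop("subject metadata rows must match dosage rows", call. = FALSE)
  if (ncol(dosage) != nrow(snps))
    stop("SNP metadata rows must match dosage columns", call. = FALSE)
  if (anyDuplicated(snps$id)) stop("SNP ids must be unique", call. = FALSE)
  if (anyDuplicated(subjects$id)) stop("subject ids must be unique", call. = FALSE)
  if (any(snps$position < 0)) stop("positions must be non-negative", call. = FALSE)
  structure(list(dosage = dosage, snps = snps, subjects = subjects),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$subjects$group)),
                                 table(x$subjects$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosage)

#' Construct a spatio-spectral feature matrix
#'
#' Subjects x (channels * frequency-components) weights: each column is the
#' strength of one data-driven spectral component at one channel for one
#' subject. Columns are channel-major: the block of `n_freq_components`
#' consecutive columns belongs to one channel.
#'
#' @param weights numeric matrix, subjects x (channels * n_freq_components).
#' @param channel_labels character vector of channel names.
#' @param n_freq_components number of spectral components.
#' @param component_spectra optional n_freq_components x bins matrix of
#'   component spectra (unit-normalized rows).
#' @param bin_freqs optional vector of bin frequencies (Hz).
#' @param provenance `"computed"` (from [group_spectral_ica()]),
#'   `"supplied"` or `"synthetic"`.
#' @return a `spectral_features` object.
#' @export
spectral_features <- function(weights, channel_labels, n_freq_components,
                              component_spectra = NULL, bin_freqs = NULL,
                              provenance = c("computed", "supplied",
                                             "synthetic")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(weights) || any(!is.finite(weights)))
    stop("`weights` must be a finite numeric matrix", call. = FALSE)
  if (ncol(weights) != length(channel_labels) * n_freq_components)
    stop("column count must equal channels x n_freq_components", call. = FALSE)
  structure(list(weights = weights, channel_labels = channel_labels,
                 n_freq_components = as.integer(n_freq_components),
                 component_spectra = component_spectra,
                 bin_freqs = bin_freqs, column_order = "channel-major",
                 provenance = provenance),
            class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf(
    "spectral_features: %d subjects x %d columns (%d channels x %d components, %s, %s)\n",
    nrow(x$weights), ncol(x$weights), length(x$channel_labels),
    x$n_freq_components, x$column_order, x$provenance))
  invisible(x)
}
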