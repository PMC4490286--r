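# End-to-end pipeline orchestration ------------------------------------------

#' Pipeline configuration
#'
#' Collects all stage thresholds (defaults are the standard analysis
#' values: subject missing rate 3%, heterozygosity 3 sd, relatedness
#' 0.1875, MAF 5%, call rate 98%, HWE 1e-5, differential missingness 1e-5,
#' LD r-squared 0.8 in 10 kb windows, prefilter alpha 0.025, |Z| >= 2
#' feature selection, association alpha 0.05 Bonferroni-corrected over
#' component pairs) plus the input mode: either a synthetic
#' [cohort_config()] or paths to a PLINK prefix and a feature-matrix TSV.
#'
#' @param synth a `cohort_config`, or NULL when loading from files.
#' @param plink_prefix,features_path input paths (ignored when `synth` is
#'   given); `features_path` is a TSV of subject rows x feature columns.
#' @param missing_max,het_sd,ibd_max sample-QC thresholds.
#' @param maf_min,call_min,hwe_alpha,diffmiss_alpha SNP-filter thresholds.
#' @param r2_max,window_bp LD-pruning parameters.
#' @param strat_components,strat_alpha stratification scan size and level.
#' @param prefilter_alpha univariate selection threshold per contrast.
#' @param order_mode_snp,order_mode_eeg `"mdl"`, `"stability"` or
#'   `"fixed"`.
#' @param k_snp,k_eeg fixed orders (used when the mode is `"fixed"`; also
#'   the stability candidate bounds center).
#' @param stability_candidates candidate orders for `"stability"` mode.
#' @param coupling a [coupling_config()].
#' @param z_threshold |Z| cutoff for component feature selection.
#' @param assoc_alpha family-wise association level.
#' @param run_reliability run the leave-one-out stage (n reruns; the
#'   costliest stage).
#' @param max_iter,tol ICA iteration settings.
#' @param seed master seed.
#' @return validated `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, plink_prefix = NULL,
                            features_path = NULL,
                            missing_max = 0.03, het_sd = 3,
                            ibd_max = 0.1875, maf_min = 0.05,
                            call_min = 0.98, hwe_alpha = 1e-5,
                            diffmiss_alpha = 1e-5, r2_max = 0.8,
                            window_bp = 10000, strat_components = 10,
                            strat_alpha = 0.05, prefilter_alpha = 0.025,
                            order_mode_snp = c("fixed", "mdl", "stability"),
                            order_mode_eeg = c("mdl", "fixed", "stability"),
                            k_snp = 9, k_eeg = 5,
                            stability_candidates = 5:12,
                            coupling = coupling_config(),
                            z_threshold = 2, assoc_alpha = 0.05,
                            run_reliability = FALSE,
                            max_iter = 1000L, tol = 1e-7, seed = 1L) {
  order_mode_snp <- match.arg(order_mode_snp)
  order_mode_eeg <- match.arg(order_mode_eeg)
  if (is.null(synth) && (is.null(plink_prefix) || is.null(features_path)))
    stop("supply either `synth` or both `plink_prefix` and `features_path`",
         call. = FALSE)
  if (!is.null(synth) && !(is.null(plink_prefix) && is.null(features_path)))
    stop("exactly one input mode: synthetic config or file paths",
         call. = FALSE)
  check_scalar_in(missing_max, "missing_max", 0, 1)
  check_scalar_in(maf_min, "maf_min", 0, 0.5)
  check_scalar_in(call_min, "call_min", 0, 1)
  check_scalar_in(hwe_alpha, "hwe_alpha", 0, 1, TRUE, TRUE)
  check_scalar_in(prefilter_alpha, "prefilter_alpha", 0, 1, TRUE, TRUE)
  check_scalar_in(assoc_alpha, "assoc_alpha", 0, 1, TRUE, TRUE)
  check_scalar_in(r2_max, "r2_max", 0, 1)
  check_scalar_in(z_threshold, "z_threshold", 0, Inf)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full association pipeline
#'
#' Stages, in order: data synthesis or loading; sample QC; SNP filters; LD
#' pruning; stratification adjustment; univariate case-control prefilter;
#' model-order selection per modality; parallel ICA on the selected,
#' adjusted, standardized SNP dosages and the EEG feature weights;
#' covariate-adjusted association testing with Bonferroni correction;
#' |Z|-based component feature selection; group and clinical comparisons;
#' optional leave-one-out reliability. Artifacts (QC report, association
#' table, component tables, manifest) are written as TSV/JSON under
#' `out_dir`; the run is deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with all stage results (`cohort`, `qc`,
#'   `prefilter`, `orders`, `fusion`, `association`, `component_features`,
#'   `group_tests`, `reliability`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("parica_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- "input"
  manifest <- list(seed = config$seed, stages = list())
  on.exit({
    manifest$failed_stage <- if (!is.null(manifest$ok) && manifest$ok)
      NULL else stage
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  })

  if (!is.null(config$synth)) {
    cohort <- generate_cohort(config$synth)
    gt <- cohort$genotypes
    feats <- cohort$features$weights
  } else {
    cohort <- NULL
    gt <- read_plink(config$plink_prefix)
    feats <- as.matrix(utils::read.delim(config$features_path,
                                         row.names = 1L))
  }

  stage <- "sample_qc"
  sq <- sample_qc(gt, config$missing_max, config$het_sd, config$ibd_max)
  kept_ids <- sq$table$subjects$id
  feats <- feats[match(kept_ids, rownames(feats)), , drop = FALSE]

  stage <- "snp_filters"
  sf <- snp_filters(sq$table, config$maf_min, config$call_min,
                    config$hwe_alpha, config$diffmiss_alpha)
  stage <- "ld_prune"
  lp <- ld_prune(sf$table, config$r2_max, config$window_bp)

  stage <- "stratification_adjust"
  sa <- stratification_adjust(lp$table, config$strat_components,
                              config$strat_alpha)

  stage <- "univariate_prefilter"
  pf <- univariate_prefilter(sa$adjusted, lp$table$subjects$group,
                             snp_ids = lp$table$snps$id,
                             alpha = config$prefilter_alpha)
  sel <- match(pf$selected, lp$table$snps$id)
  if (length(sel) < 2L)
    stop("prefilter selected fewer than 2 SNPs", call. = FALSE)
  snp_mat <- zstd_cols(sa$adjusted[, sel, drop = FALSE])
  colnames(snp_mat) <- pf$selected

  stage <- "order_selection"
  seeds <- fan_seeds(config$seed, 3L)
  pick_order <- function(mode, data, k_fixed, seed) {
    switch(mode,
           fixed = as.integer(k_fixed),
           mdl = estimate_order_mdl(data),
           stability = as.integer(estimate_order_stability(
             data, config$stability_candidates, seed = seed)))
  }
  k_snp <- pick_order(config$order_mode_snp, snp_mat, config$k_snp,
                      seeds[1L])
  k_eeg <- pick_order(config$order_mode_eeg, feats, config$k_eeg,
                      seeds[2L])
  k_snp <- max(1L, min(k_snp, nrow(snp_mat) - 1L, ncol(snp_mat)))
  k_eeg <- max(1L, min(k_eeg, nrow(feats) - 1L, ncol(feats)))

  stage <- "para_ica"
  fusion <- para_ica(snp_mat, feats, k_snp = k_snp, k_eeg = k_eeg,
                     coupling = config$coupling, seed = seeds[3L],
                     max_iter = config$max_iter, tol = config$tol)

  stage <- "association"
  covars <- lp$table$subjects[, intersect(c("age", "sex", "ethnicity",
                                            "site"),
                                          names(lp$table$subjects)),
                              drop = FALSE]
  assoc <- partial_association_matrix(fusion$eeg$loadings,
                                      fusion$snp$loadings,
                                      covariates = covars,
                                      alpha = config$assoc_alpha)

  stage <- "component_features"
  comp_snp <- zscore_select(fusion$snp, config$z_threshold,
                            feature_names = colnames(snp_mat))
  comp_eeg <- zscore_select(fusion$eeg, config$z_threshold,
                            feature_names = colnames(feats))

  stage <- "group_tests"
  sig <- assoc[assoc$significant, , drop = FALSE]
  lc_cols <- cbind(fusion$eeg$loadings[, unique(sig$eeg_comp), drop = FALSE],
                   fusion$snp$loadings[, unique(sig$snp_comp), drop = FALSE])
  grp <- NULL
  if (ncol(lc_cols)) {
    colnames(lc_cols) <- c(paste0("E", unique(sig$eeg_comp)),
                           paste0("G", unique(sig$snp_comp)))
    clin <- lp$table$subjects[, intersect(c("panss_pos", "panss_neg",
                                            "panss_gen", "sbs", "cpz"),
                                          names(lp$table$subjects)),
                              drop = FALSE]
    grp <- group_and_clinical_tests(lc_cols, lp$table$subjects$group,
                                    clinical = if (ncol(clin)) clin else
                                      NULL)
  }

  rel <- NULL
  if (isTRUE(config$run_reliability)) {
    stage <- "reliability"
    rel <- loo_reliability(snp_mat, feats, fusion,
                           pairs = if (nrow(sig)) sig else NULL)
  }

  stage <- "write_artifacts"
  qc_steps <- qc_entries_df(c(sq$entries, sf$entries, lp$entries,
                              sa$entries))
  write_tsv(qc_steps, file.path(out_dir, "qc_report.tsv"))
  jsonlite::write_json(
    list(steps = qc_steps, lambda_gc = as.list(pf$lambda_gc),
         stratification = list(flagged = sa$flagged,
                               ethnicity_p = sa$ethnicity_p,
                               case_control_p = sa$case_control_p)),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_tsv(as.data.frame(assoc), file.path(out_dir, "association.tsv"))
  for (j in seq_along(comp_snp))
    write_tsv(comp_snp[[j]],
              file.path(out_dir, sprintf("component_snp_G%d.tsv", j)))
  for (j in seq_along(comp_eeg))
    write_tsv(comp_eeg[[j]],
              file.path(out_dir, sprintf("component_eeg_E%d.tsv", j)))
  if (!is.null(grp$group_tests))
    write_tsv(grp$group_tests, file.path(out_dir, "group_tests.tsv"))
  if (!is.null(grp$clinical_tests))
    write_tsv(grp$clinical_tests, file.path(out_dir, "clinical_tests.tsv"))
  if (!is.null(rel)) {
    write_tsv(rel$per_pair, file.path(out_dir, "reliability.tsv"))
    jsonlite::write_json(list(per_pair = rel$per_pair, n_runs = rel$n_runs,
                              n_failed = rel$n_failed,
                              match_on = rel$match_on),
                         file.path(out_dir, "reliability.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest$ok <- TRUE
  manifest$k_snp <- k_snp; manifest$k_eeg <- k_eeg
  manifest$n_selected_snps <- length(sel)
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  invisible(list(cohort = cohort, qc = list(sample = sq, snp = sf,
                                            ld = lp, strat = sa),
                 prefilter = pf, orders = c(k_snp = k_snp, k_eeg = k_eeg),
                 fusion = fusion, association = assoc,
                 component_features = list(snp = comp_snp, eeg = comp_eeg),
                 group_tests = grp, reliability = rel,
                 manifest = manifest, out_dir = out_dir))
}
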