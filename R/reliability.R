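# Leave-one-out reliability of the coupled decomposition ----------------------

#' Match candidate components to a reference decomposition
#'
#' One-to-one assignment of candidate to reference components maximizing
#' the total absolute correlation (Hungarian algorithm), computed on source
#' maps by default (feature space, invariant to the subject count) or on
#' loadings. Each matched candidate's sign is flipped to agree with its
#' reference component.
#'
#' @param reference,candidate `ica_decomposition` objects on the same
#'   feature space.
#' @param on `"maps"` (source rows) or `"loadings"` (subject columns; both
#'   decompositions must then share subjects).
#' @return data frame with `reference`, `candidate` (matched index or NA),
#'   `corr` (absolute matched correlation) and `sign`; unmatched components
#'   (differing k) have NA rows.
#' @export
match_components <- function(reference, candidate,
                             on = c("maps", "loadings")) {
  on <- match.arg(on)
  R <- if (on == "maps") {
    if (ncol(reference$sources) != ncol(candidate$sources))
      stop("source maps live in different feature spaces", call. = FALSE)
    stats::cor(t(reference$sources), t(candidate$sources))
  } else {
    if (nrow(reference$loadings) != nrow(candidate$loadings))
      stop("loadings have different subject counts", call. = FALSE)
    stats::cor(reference$loadings, candidate$loadings)
  }
  asg <- solve_assignment(abs(R))
  kr <- nrow(R)
  corr <- rep(NA_real_, kr); sgn <- rep(NA_real_, kr)
  ok <- !is.na(asg)
  corr[ok] <- abs(R[cbind(which(ok), asg[ok])])
  sgn[ok] <- sign(R[cbind(which(ok), asg[ok])])
  data.frame(reference = seq_len(kr), candidate = asg, corr = corr,
             sign = sgn)
}

#' Leave-one-out reliability of a parallel ICA decomposition
#'
#' Reruns [para_ica()] once per subject on the remaining n - 1 subjects
#' with the same configuration and seeds as the original run, matches each
#' rerun's components to the original per modality (on source maps by
#' default), and reports, for each significant component pair, the mean
#' absolute matched correlation per modality across runs — the reliability
#' index.
#'
#' @param snp_data,eeg_data the matrices the original result was fitted on.
#' @param original a `para_ica_result`.
#' @param pairs data frame with columns `eeg_comp`, `snp_comp` of the pairs
#'   to report (e.g. the significant rows of an association table); when
#'   NULL the single pair with the largest absolute cross-correlation is
#'   used.
#' @param match_on `"maps"` or `"loadings"` (for loadings the left-out
#'   subject's row is dropped from the reference).
#' @param progress print a dot per completed rerun.
#' @return a `reliability_report`: `per_pair` (mean within-modality |r| for
#'   the EEG and SNP side of each pair), `per_run` (matched component and
#'   correlation for every run and modality), `n_runs`, `n_failed`,
#'   `match_on`.
#' @export
loo_reliability <- function(snp_data, eeg_data, original, pairs = NULL,
                            match_on = c("maps", "loadings"),
                            progress = FALSE) {
  match_on <- match.arg(match_on)
  stopifnot(inherits(original, "para_ica_result"))
  n <- nrow(snp_data)
  if (is.null(pairs)) {
    best <- which(abs(original$cross_corr) == max(abs(original$cross_corr)),
                  arr.ind = TRUE)[1L, ]
    pairs <- data.frame(eeg_comp = best[1L], snp_comp = best[2L])
  }
  per_run <- vector("list", n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    res_i <- para_ica(snp_data[-i, , drop = FALSE],
                      eeg_data[-i, , drop = FALSE],
                      k_snp = original$snp$k, k_eeg = original$eeg$k,
                      coupling = original$coupling, seed = original$seed,
                      max_iter = original$max_iter, tol = original$tol)
    if (!res_i$converged) failed[i] <- TRUE
    ref_snp <- original$snp; ref_eeg <- original$eeg
    if (match_on == "loadings") {
      ref_snp$loadings <- ref_snp$loadings[-i, , drop = FALSE]
      ref_eeg$loadings <- ref_eeg$loadings[-i, , drop = FALSE]
    }
    m_snp <- match_components(ref_snp, res_i$snp, on = match_on)
    m_eeg <- match_components(ref_eeg, res_i$eeg, on = match_on)
    per_run[[i]] <- data.frame(
      run = i,
      rbind(cbind(modality = "snp", m_snp),
            cbind(modality = "eeg", m_eeg)))
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  runs_df <- do.call(rbind, per_run)
  ok_runs <- which(!failed)
  per_pair <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(q) {
    es <- pairs$eeg_comp[q]; ss <- pairs$snp_comp[q]
    snp_r <- runs_df$corr[runs_df$modality == "snp" &
                            runs_df$reference == ss &
                            runs_df$run %in% ok_runs]
    eeg_r <- runs_df$corr[runs_df$modality == "eeg" &
                            runs_df$reference == es &
                            runs_df$run %in% ok_runs]
    data.frame(eeg_comp = es, snp_comp = ss,
               eeg_reliability = mean(eeg_r, na.rm = TRUE),
               snp_reliability = mean(snp_r, na.rm = TRUE))
  }))
  structure(list(per_pair = per_pair, per_run = runs_df, n_runs = n,
                 n_failed = sum(failed), match_on = match_on),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Leave-one-out reliability: %d runs (%d non-convergent), matched on %s\n",
              x$n_runs, x$n_failed, x$match_on))
  print(x$per_pair, row.names = FALSE)
  invisible(x)
}
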