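# Parallel (coupled two-modality) ICA ----------------------------------------

#' Default coupling configuration for parallel ICA
#'
#' @param entry_threshold absolute loading correlation a component pair must
#'   exceed before the coupling gradient is applied to it.
#' @param lambda_max peak coupling weight; the schedule grows linearly from 0
#'   to `lambda_max` over the first half of training. `lambda_max = 0`
#'   reduces parallel ICA to two independent Infomax runs.
#' @return list of coupling settings.
#' @export
coupling_config <- function(entry_threshold = 0.3, lambda_max = 0.5) {
  check_scalar_in(entry_threshold, "entry_threshold", 0, 1)
  check_scalar_in(lambda_max, "lambda_max", 0, Inf)
  list(entry_threshold = entry_threshold, lambda_max = lambda_max)
}

# Greedy disjoint selection of component pairs above the entry threshold:
# each component joins at most one enhanced pair, strongest |r| first.
select_coupled_pairs <- function(R, threshold) {
  idx <- which(abs(R) > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx)
  idx <- idx[order(-abs(R[idx])), , drop = FALSE]
  used_r <- logical(nrow(R)); used_c <- logical(ncol(R))
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1L]; cc <- idx[i, 2L]
    if (!used_r[r] && !used_c[cc]) {
      keep[i] <- TRUE; used_r[r] <- TRUE; used_c[cc] <- TRUE
    }
  }
  idx[keep, , drop = FALSE]
}

# Gradient of the squared Pearson correlation of loading columns u = B m_u
# and v (other modality, held fixed) with respect to m_u, where B is the
# dewhitening basis so that the loading column is u = B m_u.
corr2_grad_col <- function(u, v, B) {
  uc <- u - mean(u); vc <- v - mean(v)
  cu <- sum(uc^2); cv <- sum(vc^2)
  if (cu <= 0 || cv <= 0) return(numeric(ncol(B)))
  r <- sum(uc * vc) / sqrt(cu * cv)
  dr_du <- vc / sqrt(cu * cv) - r * uc / cu
  drop(crossprod(B, 2 * r * dr_du))
}

# Coupling update for one modality's unmixing W: the loading matrix is
# A = B %*% M with M = solve(W); ascending r^2 in M-space by dM = g e_j'
# maps to the first-order W-space update dW = -W dM W = -(W g) (W[j, ])'.
coupling_delta_w <- function(W, g, j) {
  -tcrossprod(W %*% g, W[j, ])
}

#' Parallel ICA: coupled decomposition of two modalities
#'
#' Runs one Infomax ICA per modality on the same subjects while an
#' additional coupling objective drives selected cross-modal component pairs
#' toward higher absolute correlation between their subject loadings
#' ("loading coefficients", LC). After every joint iteration the loading
#' cross-correlation matrix is computed; pairs exceeding
#' `coupling$entry_threshold` in absolute value (made disjoint greedily by
#' |r|) receive a gradient-ascent step on the squared Pearson correlation of
#' their LC columns, applied to the corresponding unmixing weights. The step
#' is scaled by a coupling weight growing linearly to `coupling$lambda_max`
#' over the first half of training, and capped so each side's coupling
#' update norm never exceeds half that side's most recent Infomax update
#' norm (so the coupling force decays as the ICAs converge). With
#' `lambda_max = 0` the result is bit-identical to two independent
#' [infomax_ica()] runs seeded with `fan_seeds(seed, 2)`.
#'
#' @param snp_data subjects x SNPs numeric matrix.
#' @param eeg_data subjects x features numeric matrix (same subjects, same
#'   order).
#' @param k_snp,k_eeg component counts per modality.
#' @param coupling list from [coupling_config()].
#' @param seed master seed; fanned to the two modality initializations.
#' @param max_iter,tol iteration cap and relative-update stopping tolerance;
#'   iteration stops when both unmixing matrices have frozen (at which point
#'   cross-correlation changes are below tolerance as well, since coupling
#'   steps are capped by the frozen update norms).
#' @param extended logical, use extended Infomax updates.
#' @return a `para_ica_result`: `snp` and `eeg` ICA decompositions,
#'   `cross_corr` (k_eeg x k_snp Pearson correlations between LC columns),
#'   a per-iteration `trace` of enhanced pairs and their r, `iterations`
#'   and `converged`.
#' @export
para_ica <- function(snp_data, eeg_data, k_snp, k_eeg,
                     coupling = coupling_config(), seed = 1L,
                     max_iter = 1000L, tol = 1e-7, extended = FALSE) {
  if (!is.matrix(snp_data) || !is.matrix(eeg_data))
    stop("modality data must be numeric matrices", call. = FALSE)
  if (nrow(snp_data) != nrow(eeg_data))
    stop("modalities must share the same subjects (row counts differ)",
         call. = FALSE)
  k_snp <- check_count(k_snp, "k_snp"); k_eeg <- check_count(k_eeg, "k_eeg")
  seeds <- fan_seeds(seed, 2L)
  st1 <- ica_state_init(snp_data, k_snp, seeds[1L])
  st2 <- ica_state_init(eeg_data, k_eeg, seeds[2L])
  trace <- vector("list", max_iter)
  half <- max_iter / 2
  it <- 0L
  while (it < max_iter && !(st1$converged && st2$converged)) {
    it <- it + 1L
    st1 <- ica_state_step(st1, tol, extended)
    st2 <- ica_state_step(st2, tol, extended)
    lambda <- coupling$lambda_max * min(1, it / half)
    if (lambda > 0) {
      A1 <- st1$wh$dewhite %*% solve(st1$W)
      A2 <- st2$wh$dewhite %*% solve(st2$W)
      R <- colcor(A2, A1)                       # k_eeg x k_snp
      pairs <- select_coupled_pairs(R, coupling$entry_threshold)
      if (nrow(pairs) > 0L) {
        trace[[it]] <- cbind(eeg = pairs[, 1L], snp = pairs[, 2L],
                             r = R[pairs])
        dW1 <- matrix(0, k_snp, k_snp)
        dW2 <- matrix(0, k_eeg, k_eeg)
        for (q in seq_len(nrow(pairs))) {
          je <- pairs[q, 1L]; js <- pairs[q, 2L]
          u <- A1[, js]; v <- A2[, je]
          g1 <- corr2_grad_col(u, v, st1$wh$dewhite)
          g2 <- corr2_grad_col(v, u, st2$wh$dewhite)
          dW1 <- dW1 + coupling_delta_w(st1$W, g1, js)
          dW2 <- dW2 + coupling_delta_w(st2$W, g2, je)
        }
        cap_apply <- function(st, dW) {
          dW <- lambda * dW
          nrm <- sqrt(sum(dW^2))
          cap <- 0.5 * st$last_step
          if (nrm > cap && nrm > 0) dW <- dW * (cap / nrm)
          st$W <- st$W + dW
          st
        }
        st1 <- cap_apply(st1, dW1)
        st2 <- cap_apply(st2, dW2)
      }
    }
  }
  dec1 <- ica_state_finish(st1)
  dec2 <- ica_state_finish(st2)
  structure(list(
    snp = dec1, eeg = dec2,
    cross_corr = colcor(dec2$loadings, dec1$loadings),
    trace = trace[seq_len(it)],
    iterations = it,
    converged = st1$converged && st2$converged,
    coupling = coupling, seed = seed, max_iter = max_iter, tol = tol),
    class = "para_ica_result")
}

#' @export
print.para_ica_result <- function(x, ...) {
  cat(sprintf("Parallel ICA: k_snp = %d, k_eeg = %d, %d subjects\n",
              x$snp$k, x$eeg$k, nrow(x$snp$loadings)))
  cat(sprintf("  %s after %d iterations; max |cross-corr| = %.3f\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, max(abs(x$cross_corr))))
  invisible(x)
}

#' Select the dominant features of each component by |Z|
#'
#' Per component, returns the features whose standardized source weight
#' passes `|Z| >= z_threshold`, ranked by |Z|, together with the relative
#' weight |Z| / max |Z| (the top feature of a component has relative
#' weight 1).
#'
#' @param decomposition an `ica_decomposition` (from [infomax_ica()] or a
#'   side of [para_ica()]).
#' @param z_threshold absolute Z cutoff (default 2).
#' @param feature_names optional character vector naming the feature axis.
#' @return list (one element per component) of data frames with columns
#'   `feature`, `z`, `relative_weight`, ordered by decreasing |Z|.
#' @export
zscore_select <- function(decomposition, z_threshold = 2,
                          feature_names = NULL) {
  Z <- decomposition$zmaps
  if (is.null(Z)) stop("decomposition has no Z-maps", call. = FALSE)
  if (is.null(feature_names)) feature_names <- as.character(seq_len(ncol(Z)))
  lapply(seq_len(nrow(Z)), function(cidx) {
    z <- Z[cidx, ]
    mx <- max(abs(z))
    sel <- which(abs(z) >= z_threshold)
    sel <- sel[order(-abs(z[sel]))]
    data.frame(feature = feature_names[sel], z = z[sel],
               relative_weight = if (length(sel)) abs(z[sel]) / mx else numeric(0),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}
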