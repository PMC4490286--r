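# Model-order selection ------------------------------------------------------

#' Minimum-description-length model order
#'
#' Selects the number of signal components in a subjects-by-features matrix
#' by minimizing the Wax-Kailath MDL criterion over the eigenvalues of the
#' sample covariance, with the number of i.i.d. samples taken as the subject
#' count. Only the `min(n - 1, p)` non-null eigenvalues enter the criterion
#' (the centered sample covariance has at most that rank).
#'
#' @param X numeric matrix, subjects x features.
#' @param k_max largest order to consider (default: rank - 2).
#' @return the selected order `k >= 0`; constant data returns 0.
#' @export
estimate_order_mdl <- function(X, k_max = NULL) {
  if (!is.matrix(X) || !is.numeric(X) || anyNA(X))
    stop("`X` must be a numeric matrix without NA", call. = FALSE)
  n <- nrow(X); p0 <- ncol(X)
  if (n < 2L || p0 < 2L) stop("need at least 2 subjects and 2 features",
                              call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  d <- svd(Xc, nu = 0L, nv = 0L)$d
  ev <- d^2 / n
  r <- min(n - 1L, p0)
  ev <- ev[seq_len(r)]
  if (max(ev) <= .Machine$double.eps) return(0L)
  ev <- pmax(ev, max(ev) * 1e-15)
  p <- r
  kmax <- min(if (is.null(k_max)) p - 2L else k_max, p - 2L)
  mdl <- vapply(0:kmax, function(k) {
    tail <- ev[(k + 1L):p]
    loglik <- -n * (p - k) * (mean(log(tail)) - log(mean(tail)))
    pen <- 0.5 * (k * (2 * p - k) + 1) * log(n)
    loglik + pen
  }, numeric(1L))
  as.integer(which.min(mdl) - 1L)
}

#' Stability-based model order (consistency / ICASSO-style)
#'
#' For each candidate order, runs Infomax ICA on `n_runs` feature-subsampled
#' replicates with fresh seeds, matches components between every pair of
#' runs on the absolute correlation of their subject loadings (Hungarian
#' assignment), and scores the candidate by the mean matched absolute
#' correlation. Returns the candidate maximizing mean stability; ties break
#' toward the smaller order.
#'
#' @param X numeric matrix, subjects x features.
#' @param k_candidates integer vector of candidate orders.
#' @param n_runs replicate ICA runs per candidate (>= 5).
#' @param subsample_frac fraction of features drawn (without replacement)
#'   per replicate.
#' @param seed master seed fanned out to replicate subsamples and ICA
#'   initializations.
#' @param max_iter,tol passed to [infomax_ica()].
#' @return integer order, with attributes `stability` (per-candidate mean
#'   score) and `low_confidence` (TRUE when all scores are low or flat, as
#'   for structureless data).
#' @export
estimate_order_stability <- function(X, k_candidates, n_runs = 10L,
                                     subsample_frac = 0.8, seed = 1L,
                                     max_iter = 300L, tol = 1e-7) {
  if (length(k_candidates) == 0L) stop("`k_candidates` must be non-empty",
                                       call. = FALSE)
  n_runs <- check_count(n_runs, "n_runs", min = 5L)
  check_scalar_in(subsample_frac, "subsample_frac", 0, 1, TRUE, FALSE)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  p <- ncol(X)
  seeds <- fan_seeds(seed, 2L * n_runs * length(k_candidates))
  si <- 0L
  stab <- numeric(length(k_candidates))
  for (ci in seq_along(k_candidates)) {
    k <- k_candidates[ci]
    loads <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      sub_seed <- seeds[si + 1L]; ica_seed <- seeds[si + 2L]; si <- si + 2L
      cols <- with_seed(sub_seed,
                        sample.int(p, max(k + 1L, round(subsample_frac * p))))
      dec <- suppressWarnings(
        infomax_ica(X[, cols, drop = FALSE], k, seed = ica_seed,
                    max_iter = max_iter, tol = tol))
      loads[[r]] <- dec$loadings
    }
    pair_scores <- c()
    for (a in seq_len(n_runs - 1L)) for (b in (a + 1L):n_runs) {
      C <- abs(colcor(loads[[a]], loads[[b]]))
      asg <- solve_assignment(C)
      pair_scores <- c(pair_scores, mean(C[cbind(seq_len(k), asg)]))
    }
    stab[ci] <- mean(pair_scores)
  }
  if (stats::sd(stab) < 1e-12 && length(stab) > 1L)
    warning("stability identical across candidates; replication may be degenerate",
            call. = FALSE)
  best <- k_candidates[which.max(stab)]   # which.max ties -> first = smallest
  low_conf <- max(stab) < 0.8 || (max(stab) - min(stab)) < 0.02
  structure(as.integer(best),
            stability = stats::setNames(stab, k_candidates),
            low_confidence = low_conf)
}
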