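# Infomax ICA core -----------------------------------------------------------
#
# Data convention throughout: X is subjects x features. The generative model
# is X = A S with A (subjects x k) the loading coefficients and S
# (k x features) the sources; independence is sought along the feature axis,
# so the subject rows act as mixed channels and features as samples.

# PCA-whiten the subject rows of centered X to k dimensions.
# Returns Z (k x p) with Z Z'/p = I, the whitening matrix K (k x n) such that
# Z = K t(Xc_rows_centered) ... here operating on rows: Z = K %*% Xc where
# Xc has row means removed, plus the dewhitening basis.
whiten_rows <- function(X, k) {
  n <- nrow(X); p <- ncol(X)
  rm_ <- rowMeans(X)
  Xc <- X - rm_
  C <- tcrossprod(Xc) / p
  e <- eigen(C, symmetric = TRUE)
  pos <- sum(e$values > max(e$values) * 1e-12)
  if (k > pos)
    stop(sprintf("k = %d exceeds the rank (%d) of the centered data", k, pos),
         call. = FALSE)
  Ek <- e$vectors[, seq_len(k), drop = FALSE]
  lam <- e$values[seq_len(k)]
  K <- sweep(t(Ek), 1L, sqrt(lam), "/")         # k x n
  dewhite <- sweep(Ek, 2L, sqrt(lam), "*")      # n x k ; A = dewhite %*% solve(W)
  list(Z = K %*% Xc, K = K, dewhite = dewhite, row_means = rm_,
       eigenvalues = e$values)
}

# One full-batch natural-gradient Infomax step. Returns the (unscaled)
# natural-gradient direction D; the caller applies W <- W + lr * D.
infomax_grad <- function(W, Z, extended = FALSE, kurt_sign = NULL) {
  p <- ncol(Z)
  U <- W %*% Z
  if (!extended) {
    Y <- 1 / (1 + exp(-U))
    (diag(nrow(W)) + ((1 - 2 * Y) %*% t(U)) / p) %*% W
  } else {
    Ksign <- diag(kurt_sign, nrow(W))
    (diag(nrow(W)) - (Ksign %*% (tanh(U) %*% t(U))) / p -
       tcrossprod(U) / p) %*% W
  }
}

# Internal mutable ICA state used by both infomax_ica and para_ica so that
# the decoupled limit of para_ica reproduces infomax_ica bit for bit.
ica_state_init <- function(X, k, seed, lr0 = 0.1) {
  wh <- whiten_rows(X, k)
  W <- with_seed(seed, diag(k) + 0.05 * matrix(stats::rnorm(k * k), k, k))
  list(wh = wh, W = W, lr = lr0, oldD = NULL, delta = Inf,
       converged = FALSE, iter = 0L, last_step = 0)
}

# One annealed Infomax iteration on a state; freezes once converged.
ica_state_step <- function(st, tol, extended = FALSE, anneal_deg = 60,
                           lr_min = 1e-6) {
  if (st$converged) return(st)
  Z <- st$wh$Z
  kurt_sign <- NULL
  if (extended) {
    U <- st$W %*% Z
    m2 <- rowMeans(U^2); m4 <- rowMeans(U^4)
    kurt_sign <- sign(m4 / m2^2 - 3)
    kurt_sign[kurt_sign == 0] <- 1
  }
  D <- infomax_grad(st$W, Z, extended, kurt_sign)
  if (!is.null(st$oldD)) {
    ang <- sum(D * st$oldD) / sqrt(sum(D^2) * sum(st$oldD^2))
    if (is.finite(ang) && ang < cos(anneal_deg * pi / 180))
      st$lr <- max(st$lr / 2, lr_min)
  }
  st$W <- st$W + st$lr * D
  st$oldD <- D
  st$iter <- st$iter + 1L
  st$last_step <- st$lr * sqrt(sum(D^2))
  st$delta <- st$last_step / sqrt(sum(st$W^2))
  if (st$delta < tol) st$converged <- TRUE
  st
}

# Assemble an IcaDecomposition from a converged (or stopped) state.
ica_state_finish <- function(st) {
  W <- st$W
  S <- W %*% st$wh$Z                        # k x p sources
  A <- st$wh$dewhite %*% solve(W)           # n x k loadings
  zmaps <- t(apply(S, 1L, function(s) (s - mean(s)) / stats::sd(s)))
  structure(list(
    loadings = A, sources = S, zmaps = zmaps, k = nrow(W),
    unmixing = W %*% st$wh$K, whitening = st$wh$K, W = W,
    row_means = st$wh$row_means, dewhite = st$wh$dewhite,
    iterations = st$iter, converged = st$converged,
    delta = st$delta), class = "ica_decomposition")
}

#' Infomax independent component analysis
#'
#' Decomposes a subjects-by-features matrix into `k` maximally independent
#' sources using PCA whitening followed by natural-gradient Infomax with a
#' logistic nonlinearity. The learning rate is annealed (halved whenever the
#' angle between successive weight updates exceeds 60 degrees) and iteration
#' stops when the relative weight-update norm falls below `tol`.
#'
#' @param X numeric matrix, subjects x features.
#' @param k number of components; must not exceed the rank of the centered
#'   data.
#' @param seed integer seed for the random unmixing initialization.
#' @param max_iter maximum number of full-batch iterations.
#' @param tol relative weight-update norm at which to stop.
#' @param extended logical; use the extended (tanh, kurtosis-sign-switching)
#'   update able to separate sub-Gaussian sources.
#' @return an `ica_decomposition`: `loadings` (subjects x k, the loading
#'   coefficients), `sources` (k x features), `zmaps` (per-component
#'   standardized source rows), the unmixing/whitening matrices, iteration
#'   count and a convergence flag. Non-convergence returns the partial
#'   result with `converged = FALSE`.
#' @export
infomax_ica <- function(X, k, seed = 1L, max_iter = 1000L, tol = 1e-7,
                        extended = FALSE) {
  if (!is.matrix(X) || !is.numeric(X) || anyNA(X))
    stop("`X` must be a numeric matrix without NA", call. = FALSE)
  k <- check_count(k, "k")
  st <- ica_state_init(X, k, seed)
  for (i in seq_len(max_iter)) {
    st <- ica_state_step(st, tol, extended)
    if (st$converged) break
  }
  dec <- ica_state_finish(st)
  if (!dec$converged)
    warning(sprintf("Infomax did not converge in %d iterations (delta = %.2e)",
                    max_iter, dec$delta), call. = FALSE)
  dec
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("Infomax ICA decomposition: %d subjects x %d features, k = %d\n",
              nrow(x$loadings), ncol(x$sources), x$k))
  cat(sprintf("  %s after %d iterations (delta %.2e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$delta))
  invisible(x)
}

#' Amari index between a true and an estimated mixing
#'
#' Permutation- and scale-invariant recovery error: 0 means the estimated
#' unmixing inverts the true mixing up to permutation and scaling; values
#' near 1 indicate no recovery.
#'
#' @param W estimated unmixing (k x n) or the product `W %*% A_true` directly
#'   when `A` is `NULL`.
#' @param A true mixing matrix (n x k), optional.
#' @return scalar in `[0, ~1]`.
#' @export
amari_index <- function(W, A = NULL) {
  P <- abs(if (is.null(A)) W else W %*% A)
  k <- nrow(P)
  if (k != ncol(P)) stop("Amari index needs a square permutation-like matrix",
                         call. = FALSE)
  if (k == 1L) return(0)
  rterm <- sum(sweep(P, 1L, apply(P, 1L, max), "/")) - k
  cterm <- sum(sweep(P, 2L, apply(P, 2L, max), "/")) - k
  (rterm + cterm) / (2 * k * (k - 1))
}
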