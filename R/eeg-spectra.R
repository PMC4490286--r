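# EEG amplitude spectra and group spectral ICA -------------------------------

#' Hamming-windowed amplitude spectra of EEG epochs
#'
#' Each epoch/channel time series is Hamming-windowed and Fourier
#' transformed; the amplitude is the square root of the one-sided,
#' window-power-normalized periodogram, so that the amplitude-squared summed
#' over all bins equals the windowed mean-square signal power (Parseval).
#' Bins below `low_cut` are removed (default 1.5 Hz, guarding low-frequency
#' drift and slow eye movements).
#'
#' @param epochs numeric array `epochs x channels x samples`, or a matrix
#'   `channels x samples` for a single epoch.
#' @param fs sampling rate in Hz.
#' @param low_cut lowest retained bin frequency in Hz.
#' @param channel_labels optional channel names.
#' @return an `epoch_spectra` object: `amplitude` array
#'   (epochs x channels x bins), `freqs` (Hz, strictly increasing),
#'   `channel_labels`, `fs`.
#' @export
spectral_transform <- function(epochs, fs, low_cut = 1.5,
                               channel_labels = NULL) {
  if (is.matrix(epochs)) epochs <- array(epochs, c(1L, dim(epochs)))
  if (length(dim(epochs)) != 3L)
    stop("`epochs` must be epochs x channels x samples", call. = FALSE)
  if (!all(is.finite(epochs))) stop("non-finite samples in epochs",
                                    call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  nt <- dim(epochs)[3L]
  if (nt < 2L) stop("epoch length must be >= 2 samples", call. = FALSE)
  if (low_cut >= fs / 2) stop("`low_cut` must be below the Nyquist frequency",
                              call. = FALSE)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nt) / (nt + 1))  # Hamming
  w2 <- sum(w^2)
  nb <- nt %/% 2L + 1L
  freqs <- (seq_len(nb) - 1L) * fs / nt
  keep <- freqs >= low_cut
  one_sided <- rep(2, nb)
  one_sided[1L] <- 1
  if (nt %% 2L == 0L) one_sided[nb] <- 1
  ne <- dim(epochs)[1L]; nc <- dim(epochs)[2L]
  amp <- array(0, c(ne, nc, sum(keep)))
  for (e in seq_len(ne)) {
    xw <- t(epochs[e, , , drop = FALSE][1L, , ]) * w      # samples x channels
    if (nc == 1L) xw <- matrix(epochs[e, 1L, ] * w, ncol = 1L)
    ft <- stats::mvfft(xw)[seq_len(nb), , drop = FALSE]
    pw <- sweep(Mod(ft)^2, 1L, one_sided, "*") / (nt * w2)
    amp[e, , ] <- t(sqrt(pw[keep, , drop = FALSE]))
  }
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d",
                                                         seq_len(nc))
  structure(list(amplitude = amp, freqs = freqs[keep],
                 channel_labels = channel_labels, fs = fs),
            class = "epoch_spectra")
}

#' Group spectral ICA: compress cohort spectra to frequency components
#'
#' All subjects' epoch/channel amplitude spectra are stacked into one
#' (subjects * epochs * channels) x bins matrix, reduced to `n_components`
#' dimensions by PCA and unmixed by Infomax. Per-subject spatio-spectral
#' weights are back-reconstructed by averaging each subject's epoch weights
#' within channel, then flattened channel-major to channels x n_components
#' columns. Component spectra are unit-normalized with the sign fixed so
#' each component's peak is positive; subject weights carry the magnitude.
#'
#' @param spectra list of `epoch_spectra`, one per subject, sharing the
#'   channel montage and bin grid.
#' @param n_components number of spectral components (default 8).
#' @param seed,max_iter,tol passed to the Infomax stage.
#' @return a `spectral_features` object with `provenance = "computed"`,
#'   including the component spectra and their peak frequencies.
#' @export
group_spectral_ica <- function(spectra, n_components = 8, seed = 1L,
                               max_iter = 1000L, tol = 1e-7) {
  if (length(spectra) < 2L) stop("need at least 2 subjects", call. = FALSE)
  n_components <- check_count(n_components, "n_components")
  freqs <- spectra[[1L]]$freqs
  ch <- spectra[[1L]]$channel_labels
  nc <- length(ch); nb <- length(freqs)
  rows <- lapply(spectra, function(sp) {
    stopifnot(identical(sp$freqs, freqs))
    a <- sp$amplitude
    matrix(aperm(a, c(2L, 1L, 3L)), ncol = nb)   # (channels*epochs) x bins
  })
  stacked <- do.call(rbind, rows)
  dec <- suppressWarnings(
    infomax_ica(stacked, n_components, seed = seed, max_iter = max_iter,
                tol = tol))
  comp <- dec$sources                            # k x bins
  # unit-normalize spectra, positive peak; weights absorb the scale
  scale_fac <- sqrt(rowSums(comp^2))
  sign_fac <- sign(comp[cbind(seq_len(n_components),
                              max.col(abs(comp)))])
  sign_fac[sign_fac == 0] <- 1
  comp <- comp / (scale_fac * sign_fac)
  A <- dec$loadings %*% diag(scale_fac * sign_fac, n_components)
  # rows of `stacked` are channel-major within epoch within subject
  n_sub <- length(spectra)
  W <- matrix(0, n_sub, nc * n_components)
  offset <- 0L
  for (s in seq_len(n_sub)) {
    ne <- dim(spectra[[s]]$amplitude)[1L]
    blk <- A[offset + seq_len(nc * ne), , drop = FALSE]
    arr <- array(blk, c(nc, ne, n_components))
    subj_w <- apply(arr, c(1L, 3L), mean)        # channels x components
    W[s, ] <- as.vector(t(subj_w))               # channel-major flatten
    offset <- offset + nc * ne
  }
  colnames(W) <- as.vector(t(outer(ch, seq_len(n_components),
                                   function(c_, k_) paste0(c_, "_ic", k_))))
  peak <- freqs[max.col(abs(comp))]
  spectral_features(W, channel_labels = ch,
                    n_freq_components = n_components,
                    component_spectra = comp, bin_freqs = freqs,
                    provenance = "computed") -> out
  out$peak_freqs <- peak
  out
}
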