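test_that("a pure sinusoid peaks at its own frequency bin", {
  fs <- 250; nt <- 500
  x <- sin(2 * pi * 10 * seq_len(nt) / fs)
  ep <- array(x, c(1, 1, nt))
  sp <- spectral_transform(ep, fs = fs)
  peak <- sp$freqs[which.max(sp$amplitude[1, 1, ])]
  expect_equal(peak, 10, tolerance = fs / nt)
  expect_true(all(sp$freqs >= 1.5))
  expect_true(all(diff(sp$freqs) > 0))
})

test_that("all-zero epochs give all-zero amplitudes", {
  sp <- spectral_transform(array(0, c(2, 3, 128)), fs = 100)
  expect_true(all(sp$amplitude == 0))
})

test_that("amplitudes satisfy Parseval for the windowed signal", {
  set.seed(5)
  nt <- 256; fs <- 128
  x <- rnorm(nt)
  sp <- spectral_transform(array(x, c(1, 1, nt)), fs = fs, low_cut = 0)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nt) / (nt + 1))
  expect_equal(sum(sp$amplitude^2), sum((w * x)^2) / sum(w^2),
               tolerance = 1e-10)
  # windowed power approximates the raw mean square for stationary noise
  expect_equal(sum(sp$amplitude^2), mean(x^2), tolerance = 0.25)
})

test_that("input validation rejects bad epochs and cutoffs", {
  expect_error(spectral_transform(array(c(1, NA), c(1, 1, 2)), fs = 10),
               "finite")
  expect_error(spectral_transform(array(0, c(1, 1, 64)), fs = 100,
                                  low_cut = 60), "Nyquist")
  expect_error(spectral_transform(array(0, c(1, 1, 1)), fs = 100), "epoch")
})

# Build synthetic cohort spectra from known band-limited component spectra.
make_band_spectra <- function(n_sub, n_epoch, n_chan, fs = 125, nt = 250,
                              seed = 1) {
  set.seed(seed)
  nb_keep <- sum((seq_len(nt %/% 2 + 1) - 1) * fs / nt >= 1.5)
  freqs <- seq_len(nb_keep)
  bands <- list(5:9, 18:24, 38:46)
  comp <- t(sapply(bands, function(b) {
    s <- numeric(nb_keep); s[b] <- dnorm(seq_along(b), mean(seq_along(b)), 2)
    s / sqrt(sum(s^2))
  }))
  mix <- abs(matrix(rnorm(n_sub * n_chan * 3, 2, 1), ncol = 3))
  spectra <- lapply(seq_len(n_sub), function(s) {
    amp <- array(0, c(n_epoch, n_chan, nb_keep))
    for (e in seq_len(n_epoch)) for (ch in seq_len(n_chan)) {
      w <- mix[(s - 1) * n_chan + ch, ] * (1 + 0.1 * rnorm(3))
      amp[e, ch, ] <- pmax(drop(w %*% comp) + 0.01 * abs(rnorm(nb_keep)), 0)
    }
    structure(list(amplitude = amp, freqs = freqs,
                   channel_labels = sprintf("ch%02d", seq_len(n_chan)),
                   fs = fs), class = "epoch_spectra")
  })
  list(spectra = spectra, comp = comp)
}

test_that("group spectral ICA recovers known band-limited components", {
  sim <- make_band_spectra(n_sub = 12, n_epoch = 4, n_chan = 6, seed = 2)
  out <- group_spectral_ica(sim$spectra, n_components = 3, seed = 4)
  expect_equal(ncol(out$weights), 6 * 3)   # channels x components
  expect_equal(out$provenance, "computed")
  C <- abs(cor(t(out$component_spectra), t(sim$comp)))
  asg <- solve_assignment(C)
  expect_true(all(C[cbind(1:3, asg)] > 0.95))
  # component spectra are unit-normalized with positive peaks
  expect_equal(rowSums(out$component_spectra^2), rep(1, 3),
               tolerance = 1e-8)
  peaks <- apply(out$component_spectra, 1, function(s) s[which.max(abs(s))])
  expect_true(all(peaks > 0))
})

test_that("rank-1 spectra yield the generating spectrum as the single component", {
  set.seed(9)
  nb <- 40
  s0 <- abs(rnorm(nb)); s0 <- s0 / sqrt(sum(s0^2))
  spectra <- lapply(1:4, function(i) {
    amp <- array(0, c(2, 2, nb))
    for (e in 1:2) for (ch in 1:2)
      amp[e, ch, ] <- runif(1, 1, 3) * s0
    structure(list(amplitude = amp, freqs = seq_len(nb),
                   channel_labels = c("a", "b"), fs = 100),
              class = "epoch_spectra")
  })
  out <- group_spectral_ica(spectra, n_components = 1, seed = 2)
  expect_gt(abs(cor(out$component_spectra[1, ], s0)), 0.999)
})

test_that("two seeds give matched components on well-separated sources", {
  sim <- make_band_spectra(n_sub = 12, n_epoch = 4, n_chan = 6, seed = 6)
  a <- group_spectral_ica(sim$spectra, 3, seed = 10)
  b <- group_spectral_ica(sim$spectra, 3, seed = 20)
  C <- abs(cor(t(a$component_spectra), t(b$component_spectra)))
  asg <- solve_assignment(C)
  expect_gt(mean(C[cbind(1:3, asg)]), 0.95)
})

test_that("feature width is always channels x n_components", {
  for (nch in c(3, 5)) {
    sim <- make_band_spectra(n_sub = 8, n_epoch = 2, n_chan = nch,
                             seed = nch)
    out <- group_spectral_ica(sim$spectra, 2, seed = 1)
    expect_equal(ncol(out$weights), nch * 2)
  }
})
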