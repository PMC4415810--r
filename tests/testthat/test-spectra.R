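# Multitaper machinery: DPSS tapers, CSD estimation, pooling, band peaks
# and the relative SNR.

test_that("DPSS tapers are orthonormal with ordered concentrations", {
  tp <- dpss_tapers(256, time_bandwidth = 2, k = 3)
  G <- crossprod(tp$tapers)
  expect_lt(max(abs(G - diag(3))), 1e-10)
  # leading Slepian sequence has no sign change
  expect_true(all(tp$tapers[, 1] > 0) || all(tp$tapers[, 1] < 0))
  # concentrations decrease and are near 1 for the leading tapers
  expect_true(all(diff(tp$eigenvalues) < 0))
  expect_gt(tp$eigenvalues[1], 0.999)
  expect_error(dpss_tapers(256, 2, 5), "exceeds")
  expect_error(dpss_tapers(4, 2, 2), "too short")
})

test_that("CSD locates a sinusoid and recovers delays in phase", {
  fs <- 128
  t <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * 3 * t)
  set.seed(2)
  xm <- rbind(x + rnorm(length(t), sd = 0.1), x + rnorm(length(t), sd = 0.1))
  cs <- multitaper_csd(xm, fs = fs)
  expect_equal(cs$freq[which.max(cs$psd[1, ])], 3)
  # delayed copy of spectrally flat noise: phase of S_xy = -2 pi f tau.
  # A flat spectrum keeps the +/- NW-bin multitaper smoothing unbiased for
  # the linear phase ramp.
  tau <- 0.05                             # 50 ms
  lag <- round(tau * fs)
  xb <- rnorm(length(t))
  y <- c(rep(0, lag), xb[1:(length(xb) - lag)])
  cs2 <- multitaper_csd(rbind(xb, y), fs = fs)
  for (f in c(2, 3, 4)) {
    i <- which(cs2$freq == f)
    ph <- Arg(cs2$csd[1, 2, i])
    expect_lt(abs(ph - 2 * pi * f * lag / fs) %% (2 * pi), 2 * pi / 180 * 2)
  }
})

test_that("white-noise CSD is Hermitian, flat and positive semidefinite", {
  set.seed(3)
  x <- matrix(rnorm(4 * 40 * 128), 4)
  cs <- multitaper_csd(x, fs = 128)
  for (f in c(5, 20, 50)) {
    M <- cs$csd[, , f]
    expect_lt(max(abs(M - Conj(t(M)))), 1e-10)
    ev <- eigen((M + Conj(t(M))) / 2, only.values = TRUE)$values
    expect_gt(min(Re(ev)), -1e-10)
  }
  # diagonal flat within 3 standard errors of the chi-squared spread
  inband <- cs$freq > 2 & cs$freq < 62
  p <- rowMeans(cs$psd[, inband])
  rel_se <- 1 / sqrt(cs$n_epochs * 3 * sum(inband))
  expect_lt(max(abs(p / mean(p) - 1)), 3 * rel_se * sqrt(sum(inband)))
  # magnitude-squared coherence bounded in [0, 1]
  for (f in c(5, 20)) {
    M <- cs$csd[, , f]
    msc <- abs(M)^2 / (Re(diag(M)) %o% Re(diag(M)))
    expect_true(all(msc <= 1 + 1e-12 & msc >= 0))
  }
})

test_that("multitaper normalization satisfies Parseval within 1%", {
  set.seed(4)
  fs <- 128; n <- fs
  x <- matrix(rnorm(2 * 50 * n), 2)
  cs <- multitaper_csd(x, fs = fs)
  tp <- dpss_tapers(n, 2, 3)
  # epoch/taper-mean variance of the tapered signal
  tv <- 0
  for (e in 0:49) for (k in 1:3) {
    seg <- x[1, (e * n + 1):((e + 1) * n)]
    tv <- tv + sum((seg * tp$tapers[, k])^2)
  }
  tv <- tv / (50 * 3)
  df <- cs$freq[2] - cs$freq[1]
  expect_equal(sum(cs$psd[1, ]) * df, tv, tolerance = 0.01)
})

test_that("pooled spectrum and band peak behave per their definitions", {
  set.seed(5)
  fs <- 128
  x <- matrix(rnorm(60 * fs), 1)[rep(1, 3), ] * c(1, 5, 10)  # scaled copies
  cs <- multitaper_csd(x, fs = fs)
  pooled <- pooled_power_spectrum(cs)
  # identical (scaled) channels: pooled equals each normalized spectrum
  expect_equal(pooled$power, cs$psd[1, ] / sum(cs$psd[1, ]), tolerance = 1e-10)
  # single spectral line: band contains the line
  t <- (0:(60 * fs - 1)) / fs
  xs <- rbind(sin(2 * pi * 3 * t) + rnorm(length(t), sd = 0.05))
  ps <- pooled_power_spectrum(multitaper_csd(xs, fs = fs))
  bp <- find_band_peak(ps, c(1, 8))
  expect_true(bp[1] <= 3 && bp[2] >= 3)
  # flat spectrum: warning and full range
  flat <- list(freq = 0:20, power = rep(1, 21))
  expect_warning(bpf <- find_band_peak(flat, c(1, 4)), "flat")
  expect_equal(bpf, c(1, 4))
})

test_that("relative SNR matches the analytic scaling oracle", {
  set.seed(6)
  fs <- 128
  x <- matrix(rnorm(4 * 30 * fs), 4)
  x <- bandpass_filtfilt(x, fs, c(1, 4))
  expect_equal(relative_snr_db(x, x, fs = fs), 0, tolerance = 1e-9)
  # amplitude ratio 63.1 -> 10 log10(63.1^2) = 36.0 dB
  expect_equal(relative_snr_db(63.1 * x, x, fs = fs), 20 * log10(63.1),
               tolerance = 0.1)
})
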