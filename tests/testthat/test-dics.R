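# DICS beamformer: filters, power and coherence maps, source iteration and
# signal extraction.

# small helper: sensor data + band CSD for dipoles at given grid indices
dipole_csd <- function(fwd, idx, amps, n_sec = 40, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  fs <- 128
  n <- n_sec * fs
  pts <- fwd$grid$points
  y <- matrix(0, 19, n)
  sigs <- matrix(0, length(idx), n)
  for (j in seq_along(idx)) {
    s <- bandpass_filtfilt(rnorm(n), fs, c(1, 4))
    s <- s / sd(s) * amps[j]
    sigs[j, ] <- s
    u <- pts[idx[j], ] / sqrt(sum(pts[idx[j], ]^2))
    g <- drop(fwd$leadfield$gain[, idx[j], ] %*% u)
    y <- y + outer(g, s)
  }
  y <- apply_average_reference(y + matrix(rnorm(19 * n, sd = noise_sd), 19))
  list(y = y, fs = fs, C = band_csd(multitaper_csd(y, fs = fs)), sigs = sigs)
}

test_that("spatial filter satisfies unit gain and reduces to least squares", {
  fwd <- fx_forward_coarse()
  d <- dipole_csd(fwd, 20, 30)
  L <- fwd$leadfield$gain[, 15, ]
  flt <- dics_spatial_filter(d$C, L, lambda = 0.05)
  expect_lt(max(Mod(flt$A %*% L - diag(3))), 1e-8)
  expect_lt(max(abs(flt$A_real %*% L - diag(3))), 1e-8)
  # identity CSD with orthonormalized leadfield: filter = pseudo-inverse
  Q <- qr.Q(qr(L))
  flt2 <- dics_spatial_filter(diag(19) + 0i, Q, lambda = 0)
  expect_lt(max(Mod(flt2$A - t(Q))), 1e-8)
})

test_that("beamformer output variance is minimal at the true source", {
  fwd <- fx_forward_coarse()
  pts <- fwd$grid$points
  src <- which.min(rowSums(sweep(pts, 2, c(20, -20, 30), "-")^2))
  d <- dipole_csd(fwd, src, 40, seed = 2)
  # filter built FOR the true location has lower output power than filters
  # built for the true location but evaluated elsewhere is not meaningful;
  # the minimum-variance property: among unit-gain filters for location r,
  # the adaptive filter has minimal variance. Check empirically: the
  # adaptive filter's output power <= power of the non-adaptive
  # (pseudo-inverse) unit-gain filter at the same location.
  L <- fwd$leadfield$gain[, src, ]
  ad <- dics_spatial_filter(d$C, L, lambda = 0.001)
  na <- dics_spatial_filter(diag(19) + 0i, L, lambda = 0)
  p_ad <- Re(sum(diag(ad$A %*% d$C %*% Conj(t(ad$A)))))
  p_na <- Re(sum(diag(na$A %*% d$C %*% Conj(t(na$A)))))
  expect_lte(p_ad, p_na * (1 + 1e-8))
})

test_that("power map localizes a single dipole and scales linearly", {
  fwd <- fx_forward()
  pts <- fwd$grid$points
  src <- which.min(rowSums(sweep(pts, 2, c(-20, 10, 30), "-")^2))
  d <- dipole_csd(fwd, src, 50, seed = 3)
  pm <- source_power_map(d$C, fwd$leadfield)
  i <- which.max(pm$nai)
  expect_lte(sqrt(sum((pts[i, ] - pts[src, ])^2)), fwd$grid$spacing)
  # scaling the CSD scales all powers
  pm2 <- source_power_map(3 * d$C, fwd$leadfield)
  expect_equal(pm2$power, 3 * pm$power, tolerance = 1e-9)
  # reference selection: global maximum, deterministic tie-break
  expect_equal(as.integer(select_reference(pm)), i)
  pmtie <- pm; pmtie$nai <- rep(1, length(pm$nai))
  expect_equal(as.integer(select_reference(pmtie)), 1L)
})

test_that("coherence map is bounded and peaks at a coupled second dipole", {
  fwd <- fx_forward()
  pts <- fwd$grid$points
  s1 <- which.min(rowSums(sweep(pts, 2, c(0, -30, 40), "-")^2))
  s2 <- which.min(rowSums(sweep(pts, 2, c(30, 10, 30), "-")^2))
  # two coherent dipoles: second is a lagged copy plus noise
  set.seed(4)
  fs <- 128; n <- 40 * fs
  a <- bandpass_filtfilt(rnorm(n), fs, c(1, 4))
  b <- 0.8 * c(rep(0, 8), a[1:(n - 8)]) +
    0.6 * bandpass_filtfilt(rnorm(n), fs, c(1, 4))
  mk <- function(i, s) {
    u <- pts[i, ] / sqrt(sum(pts[i, ]^2))
    outer(drop(fwd$leadfield$gain[, i, ] %*% u), s / sd(s))
  }
  y <- apply_average_reference(40 * mk(s1, a) + 30 * mk(s2, b) +
                                 matrix(rnorm(19 * n, sd = 1), 19))
  C <- band_csd(multitaper_csd(y, fs = fs))
  pm <- source_power_map(C, fwd$leadfield)
  cm <- source_coherence_map(pm, s1)
  expect_true(all(cm$coherence >= 0 & cm$coherence <= 1))
  expect_equal(cm$coherence[s1], 1)
  # secondary peak within one spacing of the second dipole
  far <- sqrt(rowSums(sweep(pts, 2, pts[s1, ], "-")^2)) > 20
  i2 <- which(far)[which.max(cm$coherence[far])]
  expect_lte(sqrt(sum((pts[i2, ] - pts[s2, ])^2)), 2 * fwd$grid$spacing)
})

test_that("source iteration respects threshold, cap and exclusion", {
  fwd <- fx_forward_coarse()
  d <- dipole_csd(fwd, c(10, 40), c(40, 30), seed = 5)
  pm <- source_power_map(d$C, fwd$leadfield)
  # threshold 1.0: nothing can exceed the coherence bound -> reference only
  only_ref <- iterate_coherent_sources(pm, 1.0)
  expect_equal(nrow(only_ref$sources), 1L)
  expect_equal(only_ref$sources$role, "reference")
  # permissive threshold: sources are separated by the exclusion radius
  srcs <- iterate_coherent_sources(pm, 0.05, exclusion_mm = 25)
  if (nrow(srcs$sources) > 1) {
    D <- as.matrix(dist(as.matrix(srcs$sources[, c("x", "y", "z")])))
    expect_true(all(D[upper.tri(D)] > 25))
  }
  expect_lte(nrow(srcs$sources), 8)
})

test_that("extracted source signals track the true waveform", {
  fwd <- fx_forward()
  pts <- fwd$grid$points
  src <- which.min(rowSums(sweep(pts, 2, c(20, 20, 30), "-")^2))
  d <- dipole_csd(fwd, src, 60, noise_sd = 0.3, seed = 6)
  pm <- source_power_map(d$C, fwd$leadfield)
  srcs <- iterate_coherent_sources(pm, 1.0)    # reference only
  sig <- extract_source_signals(d$y, srcs, fwd$leadfield)
  expect_equal(nrow(sig), 1L)
  expect_gte(abs(cor(sig[1, ], d$sigs[1, ])), 0.9)
  # zero input -> zero output
  expect_equal(max(abs(extract_source_signals(0 * d$y, srcs, fwd$leadfield))), 0)
  expect_error(extract_source_signals(d$y[1:5, ], srcs, fwd$leadfield),
               "channels")
})
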