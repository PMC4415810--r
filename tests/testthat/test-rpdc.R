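# MVAR fitting, renormalized partial directed coherence, bootstrap and the
# time-reversal test.

mk_var2 <- function() {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.5
  A[2, 1, 1] <- 0.4; A[2, 1, 2] <- 0.25
  structure(list(A = A, Sigma = diag(2), order = 2L, K = 2L, fs = 32),
            class = "mvar_model")
}

test_that("MVAR fit recovers known coefficients and selects sane orders", {
  x <- simulate(mk_var2(), nsim = 1920, seed = 1)
  m <- fit_mvar(x, order = 2, fs = 32)
  expect_lte(sqrt(mean((m$A - mk_var2()$A)^2)), 0.05)
  expect_lt(m$spectral_radius, 1)
  # order selection lands on the true order (or adjacent)
  msel <- fit_mvar(x, max_order = 8, fs = 32)
  expect_true(msel$order %in% 1:4)
  # independent white noise: selected order 0 or negligible coefficients
  set.seed(2)
  w <- matrix(rnorm(3 * 1500), 3)
  mw <- fit_mvar(w, max_order = 6, fs = 32)
  if (mw$order > 0) {
    se <- sqrt(diag(mw$Rinv)[1] * max(diag(mw$Sigma)) / mw$n_eff)
    expect_true(all(abs(mw$A) < 3 * max(se, 0.08)))
  } else succeed()
  # refitting the model's own output recovers coefficients
  x2 <- simulate(m, nsim = 4000, seed = 3)
  m2 <- fit_mvar(x2, order = 2, fs = 32)
  expect_lte(sqrt(mean((m2$A - m$A)^2)), 0.06)
})

test_that("RPDC separates directed influence with a calibrated null", {
  x <- simulate(mk_var2(), nsim = 1920, seed = 4)
  m <- fit_mvar(x, order = 2, fs = 32)
  rp <- compute_rpdc(m, freqs = 1:4)
  lam <- burstnet:::band_mean_rpdc(rp)
  expect_gt(lam[2, 1], rp$chi2_threshold)     # true direction 1 -> 2
  expect_lt(lam[1, 2], rp$chi2_threshold)     # no reverse influence
  expect_true(all(is.na(diag(rp$lambda[, , 1]))))
  expect_error(compute_rpdc(fit_mvar(x, order = 0, fs = 32)), "order-0")
  # relabeling equivariance: permuting channels permutes lambda
  xp <- x[2:1, ]
  rp2 <- compute_rpdc(fit_mvar(xp, order = 2, fs = 32), freqs = 1:4)
  lam2 <- burstnet:::band_mean_rpdc(rp2)
  expect_equal(lam2[1, 2], lam[2, 1], tolerance = 1e-8)
  expect_equal(lam2[2, 1], lam[1, 2], tolerance = 1e-8)
})

test_that("pointwise type-I error of the chi-squared threshold is calibrated", {
  # Monte-Carlo calibration at alpha = 0.01 over independent-noise fits
  set.seed(5)
  nex <- 0; ntot <- 0
  for (r in 1:60) {
    x <- matrix(rnorm(3 * 1920), 3)
    rp <- compute_rpdc(fit_mvar(x, order = 3, fs = 32), freqs = 1:4)
    v <- rp$lambda[!is.na(rp$lambda)]
    nex <- nex + sum(v > rp$chi2_threshold)
    ntot <- ntot + length(v)
  }
  expect_gt(nex / ntot, 0.002)
  expect_lt(nex / ntot, 0.03)
})

test_that("bootstrap thresholds are reproducible and separate coupling", {
  x <- simulate(mk_var2(), nsim = 1920, seed = 6)
  b1 <- bootstrap_threshold(x, fs = 32, order = 2, n_boot = 100, seed = 9)
  b2 <- bootstrap_threshold(x, fs = 32, order = 2, n_boot = 100, seed = 9)
  expect_identical(b1$threshold, b2$threshold)
  lam <- burstnet:::band_mean_rpdc(compute_rpdc(fit_mvar(x, order = 2, fs = 32),
                                                1:4))
  expect_gt(lam[2, 1], b1$threshold[2, 1])    # coupled pair exceeds its null
  expect_error(bootstrap_threshold(x, fs = 32, order = 2, n_boot = 50),
               "at least 100")
})

test_that("time reversal confirms lagged causality and rejects mixtures", {
  # lagged causal pair
  x <- simulate(mk_var2(), nsim = 1920, seed = 7)
  boot <- bootstrap_threshold(x, fs = 32, order = 2, n_boot = 100, seed = 10)
  ed <- time_reversal_test(x, fs = 32, order = 2, boot = boot)
  causal <- ed[ed$from == 1 & ed$to == 2, ]
  expect_equal(causal$trt, "strong_asymmetry_confirmed")
  expect_true(causal$accepted)
  reverse <- ed[ed$from == 2 & ed$to == 1, ]
  expect_false(reverse$accepted)
  # instantaneous mixture of one source onto two channels: no acceptance
  set.seed(8)
  s <- as.numeric(stats::filter(rnorm(2100), 0.6, method = "recursive"))[101:2100]
  mix <- rbind(s + 0.5 * rnorm(2000), 0.6 * s + 0.5 * rnorm(2000))
  bm <- bootstrap_threshold(mix, fs = 32, order = 3, n_boot = 100, seed = 11)
  em <- time_reversal_test(mix, fs = 32, order = 3, boot = bm)
  expect_false(any(em$accepted))
})

test_that("decimation preserves the delta band", {
  set.seed(9)
  fs <- 512
  t <- (0:(20 * fs - 1)) / fs
  x <- rbind(sin(2 * pi * 2.5 * t), cos(2 * pi * 3.5 * t))
  d <- decimate_signals(x, fs, 32)
  expect_equal(d$fs, 32)
  expect_equal(ncol(d$signals), 20 * 32)
  td <- (0:(20 * 32 - 1)) / 32
  expect_gt(cor(d$signals[1, 200:400], sin(2 * pi * 2.5 * td)[200:400]), 0.99)
  expect_error(decimate_signals(x, 500, 32), "integer multiple")
})
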