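# Surrogate source significance, Friedman test and the phase contrast.

test_that("Friedman test matches the brute-force rank definition", {
  # identical condition columns
  m0 <- matrix(rep(c(1, 2, 3), 3), 3, 3)
  r0 <- friedman_phase_test(m0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # random integer tables against the independent rank-definition oracle
  set.seed(10)
  for (i in 1:50) {
    m <- matrix(sample(1:4, 12, replace = TRUE), 4, 3)
    got <- friedman_phase_test(m)
    want <- friedman_bruteforce(m)
    if (want$statistic == 0) {
      expect_equal(got$statistic, 0)
    } else if (is.nan(got$statistic)) {
      # fully tied within every row: degenerate for both definitions
      expect_equal(want$statistic, 0)
    } else {
      expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    }
  }
  expect_error(friedman_phase_test(matrix(1, 1, 3)), "at least 2")
})

test_that("two-condition Friedman agrees with the sign test at large n", {
  set.seed(11)
  agree <- 0
  for (i in 1:100) {
    d <- matrix(rnorm(40), 20, 2)
    d[, 1] <- d[, 1] + 0.4
    f <- friedman_phase_test(d)
    s <- stats::binom.test(sum(d[, 1] > d[, 2]), 20)$p.value
    agree <- agree + ((f$p_value < 0.05) == (s < 0.05))
  }
  expect_gte(agree, 85)
})

test_that("surrogate threshold is deterministic and detects coupled dipoles", {
  fwd <- fx_forward_coarse()
  # coherent two-dipole simulation
  set.seed(12)
  fs <- 128; n <- 40 * fs
  pts <- fwd$grid$points
  s1 <- which.min(rowSums(sweep(pts, 2, c(0, -30, 40), "-")^2))
  s2 <- which.min(rowSums(sweep(pts, 2, c(30, 10, 20), "-")^2))
  a <- bandpass_filtfilt(rnorm(n), fs, c(1, 4))
  b <- 0.9 * c(rep(0, 6), a[1:(n - 6)]) +
    0.4 * bandpass_filtfilt(rnorm(n), fs, c(1, 4))
  mk <- function(i, s) {
    u <- pts[i, ] / sqrt(sum(pts[i, ]^2))
    outer(drop(fwd$leadfield$gain[, i, ] %*% u), s / sd(s))
  }
  y <- apply_average_reference(40 * mk(s1, a) + 35 * mk(s2, b) +
                                 matrix(rnorm(19 * n, sd = 1), 19))
  seg <- structure(list(data = y, fs = fs, phase = "burst",
                        intervals = list(c(0, n)), joins = integer(0)),
                   class = "phase_segments")
  sur <- surrogate_source_threshold(seg, fwd$leadfield, n_perm = 40, seed = 3)
  expect_gt(sur$observed, sur$threshold)
  expect_lt(sur$p_value, 0.05)
  sur2 <- surrogate_source_threshold(seg, fwd$leadfield, n_perm = 40, seed = 3)
  expect_identical(sur$threshold, sur2$threshold)
  expect_error(surrogate_source_threshold(seg, fwd$leadfield, n_perm = 10),
               "at least 20")
})

test_that("phase contrast reports direction and significance", {
  # synthetic per-subject results with a strong burst advantage
  mk_subj <- function(i, pb, ps, cb, cs) {
    structure(list(subject = i,
                   phases = list(
                     burst = list(mean_source_power = pb,
                                  mean_source_coherence = cb),
                     suppression = list(mean_source_power = ps,
                                        mean_source_coherence = cs))),
              class = "bs_subject")
  }
  set.seed(13)
  subs <- lapply(1:13, function(i)
    mk_subj(i, pb = 100 * runif(1, 0.5, 2), ps = 0.01 * runif(1, 0.5, 2),
            cb = 0.4 + 0.1 * runif(1), cs = 0.1 + 0.05 * runif(1)))
  ct <- compare_phases(subs)
  expect_equal(ct$power_direction, "burst > suppression")
  expect_equal(ct$coherence_direction, "burst > suppression")
  expect_lt(ct$power_test$p_value, 0.01)
  expect_lt(ct$coherence_test$p_value, 0.01)
  # identical phases: p = 1
  same <- lapply(1:5, function(i) mk_subj(i, 1, 1, 0.2, 0.2))
  ct2 <- compare_phases(same)
  expect_equal(ct2$power_test$p_value, 1)
})
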