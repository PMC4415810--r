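# Forward model: montage geometry, shell model validation, source grid and
# the analytic dipole solution against its closed-form oracle.

test_that("10-20 montage has the canonical geometry", {
  m <- standard_montage_1020(19)
  expect_equal(sort(m$labels),
               sort(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                      "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")))
  # Cz is the vertex
  expect_equal(unname(m$positions["Cz", ]), c(0, 0, 70), tolerance = 1e-12)
  # all electrodes on the scalp sphere
  expect_equal(unname(sqrt(rowSums(m$positions^2))), rep(70, 19),
               tolerance = 1e-9)
  # left/right homologous pairs mirror about the sagittal plane
  pairs <- rbind(c("Fp1", "Fp2"), c("F7", "F8"), c("F3", "F4"), c("T3", "T4"),
                 c("C3", "C4"), c("T5", "T6"), c("P3", "P4"), c("O1", "O2"))
  for (i in seq_len(nrow(pairs))) {
    l <- m$positions[pairs[i, 1], ]; r <- m$positions[pairs[i, 2], ]
    expect_equal(unname(l * c(-1, 1, 1)), unname(r), tolerance = 1e-9)
  }
  # outer ring at 72 degrees inclination
  ring <- c("Fp1", "Fp2", "F7", "F8", "T3", "T4", "T5", "T6", "O1", "O2")
  expect_equal(unname(m$positions[ring, "z"]), rep(70 * cos(72 * pi / 180), 10),
               tolerance = 1e-9)
  # 21-channel variant adds the midline pair
  m21 <- standard_montage_1020(21)
  expect_true(all(c("Fpz", "Oz") %in% m21$labels))
  expect_error(standard_montage_1020(32), "unsupported")
})

test_that("sphere model validates its inputs", {
  m <- build_sphere_model()
  expect_s3_class(m, "sphere_model")
  expect_length(m$radii, 5)
  expect_error(build_sphere_model(radii = c(60, 58, 62, 65, 70)), "increasing")
  expect_error(build_sphere_model(conductivities = c(0.33, 0, 1.79, 0.04, 0.33)),
               "positive")
  expect_error(build_sphere_model(radii = c(58, 60, 62, 65)), "exactly 5")
})

test_that("source grid matches brute-force lattice enumeration", {
  model <- fx_model()
  g <- build_source_grid(model, 10)
  # oracle: enumerate the full lattice and clip
  ax <- 10 * (-5:5)
  full <- expand.grid(ax, ax, ax)
  keep <- sqrt(rowSums(full^2)) < 58 - 5
  expect_equal(nrow(g$points), sum(keep))
  expect_true(all(sqrt(rowSums(g$points^2)) < 58 - 5))
  expect_false(any(duplicated(g$points)))
  # cubic symmetry: invariant under axis permutation
  p1 <- g$points[order(g$points[, 1], g$points[, 2], g$points[, 3]), ]
  p2 <- g$points[, c(2, 3, 1)]
  p2 <- p2[order(p2[, 1], p2[, 2], p2[, 3]), ]
  expect_equal(unname(p1), unname(p2))
  expect_error(build_source_grid(model, 200), "spacing")
})

test_that("multishell dipole solution matches the homogeneous closed form", {
  mont <- fx_montage()
  mh <- build_sphere_model(conductivities = rep(0.33, 5))
  for (case in list(list(l = c(20, -30, 25), m = c(30, 10, -20)),
                    list(l = c(0, 0, 45), m = c(0, 0, 80)),
                    list(l = c(-35, 10, 20), m = c(5, -40, 12)))) {
    v_series <- dipole_potential(mh, mont, case$l, case$m, tol = 1e-12)
    v_closed <- dipole_potential_homogeneous(mont, case$l, case$m, 70, 0.33)
    expect_lt(max(abs(v_series - v_closed)) / max(abs(v_closed)), 1e-6)
  }
})

test_that("dipole potential has the required physical structure", {
  model <- fx_model(); mont <- fx_montage()
  # zero moment -> zero everywhere
  expect_equal(unname(dipole_potential(model, mont, c(10, 10, 10), c(0, 0, 0))),
               rep(0, 19))
  # location outside the innermost shell is rejected
  expect_error(dipole_potential(model, mont, c(0, 0, 60), c(0, 0, 1)),
               "outside")
  # superposition to machine precision
  va <- dipole_potential(model, mont, c(15, -20, 30), c(1, 0, 0))
  vb <- dipole_potential(model, mont, c(15, -20, 30), c(0, 2, 1))
  vab <- dipole_potential(model, mont, c(15, -20, 30), c(1, 2, 1))
  expect_lt(max(abs(va + vb - vab)), 1e-12 * max(abs(vab)))
  # tangential dipole on the z-axis: antisymmetric under reflection through
  # the y-z plane (moment along x)
  v <- dipole_potential(model, mont, c(0, 0, 30), c(50, 0, 0))
  expect_lt(abs(v["Fp1"] + v["Fp2"]), 1e-9)
  expect_lt(abs(v["C3"] + v["C4"]), 1e-9)
  expect_lt(abs(v["O1"] + v["O2"]), 1e-9)
  # lowering skull conductivity attenuates the scalp potential
  lo <- build_sphere_model(conductivities = c(0.33, 0.33, 1.79, 0.02, 0.33))
  v_hi <- dipole_potential(model, mont, c(0, 0, 30), c(0, 0, 50))
  v_lo <- dipole_potential(lo, mont, c(0, 0, 30), c(0, 0, 50))
  expect_lt(max(abs(v_lo)), max(abs(v_hi)))
})

test_that("lead field is average-referenced, linear and converged", {
  fwd <- fx_forward_coarse()
  lf <- fwd$leadfield
  # every column sums to ~0 across electrodes
  cs <- apply(lf$gain, c(2, 3), sum)
  expect_lt(max(abs(cs)), 1e-9)
  expect_true(all(is.finite(lf$gain)))
  # doubling a moment doubles the projection
  g <- lf$gain[, 5, ]
  m1 <- drop(g %*% c(1, 2, -1)); m2 <- drop(g %*% c(2, 4, -2))
  expect_equal(2 * m1, m2, tolerance = 1e-12)
  # adaptive truncation agrees with fixed 200 terms
  lf200 <- compute_leadfield(fwd$model, fwd$montage, fwd$grid,
                             n_terms = 200, tol = 0)
  expect_lt(max(abs(lf$gain - lf200$gain)) / max(abs(lf200$gain)), 1e-6)
})

test_that("average reference zeroes channel means and is idempotent", {
  x <- matrix(5, 4, 100)
  expect_equal(apply_average_reference(x), matrix(0, 4, 100))
  set.seed(1)
  y <- matrix(rnorm(19 * 50), 19)
  y1 <- apply_average_reference(y)
  expect_lt(max(abs(colMeans(y1))), 1e-12)
  expect_equal(apply_average_reference(y1), y1, tolerance = 1e-12)
  expect_error(apply_average_reference(matrix(1, 1, 10)), "2 channels")
})
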