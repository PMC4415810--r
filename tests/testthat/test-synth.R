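# Synthetic burst-suppression generator: dynamics, calibration, cohort.

test_that("network dynamics are delta-band, phase-specific and seeded", {
  spec <- default_network_spec()
  x <- simulate_network_dynamics(spec, "burst", 30, 512, seed = 11)
  x2 <- simulate_network_dynamics(spec, "burst", 30, 512, seed = 11)
  expect_identical(x, x2)
  # >= 60% of each active node's power in 1-4 Hz
  act <- which(spec$nodes$burst_sd > 0)
  for (k in act) {
    sp <- stats::spec.pgram(x[k, ], plot = FALSE, taper = 0)
    f <- sp$freq * 512
    expect_gt(sum(sp$spec[f >= 1 & f <= 4]) / sum(sp$spec), 0.6)
  }
  # deep nodes silent in suppression
  xs <- simulate_network_dynamics(spec, "suppression", 10, 512, seed = 11)
  expect_equal(var(xs[9, ]), 0)
  expect_equal(var(xs[10, ]), 0)
  # all-zero amplitudes give zero signals
  spec0 <- spec
  spec0$nodes$burst_sd[] <- 0
  expect_equal(max(abs(simulate_network_dynamics(spec0, "burst", 5, 512,
                                                 seed = 1))), 0)
  # instability is caught before simulation
  bad <- spec
  bad$A_burst[1, 1, 1] <- 1.2
  expect_error(simulate_network_dynamics(bad, "burst", 5, 512, seed = 1),
               "unstable")
})

test_that("network spec enforces its invariants", {
  spec <- default_network_spec()
  expect_lt(burstnet:::companion_spectral_radius(spec$A_burst), 1)
  expect_lt(burstnet:::companion_spectral_radius(spec$A_supp), 1)
  deep <- which(spec$nodes$deep)
  expect_true(all(spec$A_supp[deep, , ] == 0))
  expect_true(all(spec$A_supp[, deep, ] == 0))
  # nodes inside the innermost shell; unit orientations
  r <- sqrt(rowSums(as.matrix(spec$nodes[, c("x", "y", "z")])^2))
  expect_true(all(r < 58))
  o <- sqrt(rowSums(as.matrix(spec$nodes[, c("ox", "oy", "oz")])^2))
  expect_equal(unname(o), rep(1, nrow(spec$nodes)), tolerance = 1e-12)
  # directed burst edge list mirrors the ascending/posterior-anterior chain
  expect_true(all(c("brainstem", "thalamus", "precuneus", "somatosensory")
                  %in% spec$true_edges$from))
})

test_that("projection is linear and noise-free zeros stay zero", {
  spec <- default_network_spec()
  G <- node_gains(spec, fx_model(), fx_montage())
  expect_equal(dim(G), c(19, 10))
  x <- simulate_network_dynamics(spec, "burst", 4, 512, seed = 2)
  y0 <- project_sources(0 * x, G, noise_sd = 0)
  expect_equal(max(abs(y0)), 0)
  y1 <- project_sources(x, G, noise_sd = 0)
  y2 <- project_sources(2 * x, G, noise_sd = 0)
  expect_equal(2 * y1, y2, tolerance = 1e-12)
  # single active node: rank-1 scalp pattern
  x1 <- 0 * x; x1[1, ] <- x[1, ]
  ysing <- project_sources(x1, G, noise_sd = 0)
  expect_lt(svd(ysing)$d[2] / svd(ysing)$d[1], 1e-10)
  expect_error(project_sources(x[1:3, ], G), "do not match")
})

test_that("assembled recordings meet the clinical amplitude definition", {
  sim <- fx_recording(7)
  gt <- sim$ground_truth
  expect_gte(gt$measured$burst_pp, 150)
  expect_lte(gt$measured$burst_pp, 350)
  expect_lt(gt$measured$supp_pp, 25)
  expect_equal(gt$measured$snr_db, 37.4, tolerance = 0.5)
  # annotations alternate and tile the record
  ann <- sim$recording$annotations
  expect_true(all(diff(ann$onset) > 0))
  expect_gte(sum(ann$duration[ann$label == "burst"]), 60)
  expect_gte(sum(ann$duration[ann$label == "suppression"]), 60)
  # determinism: same seed gives a bit-identical recording
  sim2 <- assemble_burst_suppression(seed = 7, model = fx_model(),
                                     montage = fx_montage())
  expect_identical(sim2$recording$data, sim$recording$data)
})

test_that("cohort jitter keeps nodes inside the shell and is reproducible", {
  coh <- simulate_cohort(3, model = fx_model(), montage = fx_montage(),
                         seed = 5, n_bursts = 8)
  expect_length(coh, 3)
  for (s in coh) {
    r <- sqrt(rowSums(as.matrix(s$ground_truth$nodes[, c("x", "y", "z")])^2))
    expect_true(all(r < 58))
    expect_gte(s$ground_truth$measured$burst_pp, 150)
  }
  # distinct subjects, reproducible master seed
  expect_false(identical(coh[[1]]$recording$data, coh[[2]]$recording$data))
  coh2 <- simulate_cohort(3, model = fx_model(), montage = fx_montage(),
                          seed = 5, n_bursts = 8)
  expect_identical(coh[[2]]$recording$data, coh2[[2]]$recording$data)
})
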