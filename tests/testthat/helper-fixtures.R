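# Shared fixtures, built once per test run.  Coarse settings keep the unit
# suite fast; the acceptance tests use the study-scale configuration.

fx <- new.env()

fx_model <- function() {
  if (is.null(fx$model)) fx$model <- build_sphere_model()
  fx$model
}

fx_montage <- function() {
  if (is.null(fx$montage)) fx$montage <- standard_montage_1020(19)
  fx$montage
}

# full-resolution forward stack (10 mm grid) shared by dics/stats/acceptance
fx_forward <- function() {
  if (is.null(fx$fwd)) {
    model <- fx_model(); montage <- fx_montage()
    grid <- build_source_grid(model, 10)
    fx$fwd <- list(model = model, montage = montage, grid = grid,
                   leadfield = compute_leadfield(model, montage, grid))
  }
  fx$fwd
}

# coarse forward stack (20 mm grid) for cheap map tests
fx_forward_coarse <- function() {
  if (is.null(fx$fwdc)) {
    model <- fx_model(); montage <- fx_montage()
    grid <- build_source_grid(model, 20)
    fx$fwdc <- list(model = model, montage = montage, grid = grid,
                    leadfield = compute_leadfield(model, montage, grid))
  }
  fx$fwdc
}

fx_recording <- function(seed = 7) {
  key <- paste0("rec", seed)
  if (is.null(fx[[key]]))
    fx[[key]] <- assemble_burst_suppression(seed = seed,
                                            model = fx_model(),
                                            montage = fx_montage())
  fx[[key]]
}

# white-noise multichannel recording helper
white_recording <- function(seed, n_sec = 30, fs = 512, C = 19, sd = 1) {
  set.seed(seed)
  data <- matrix(rnorm(C * n_sec * fs, sd = sd), C)
  structure(list(data = apply_average_reference(data), fs = fs,
                 channels = fx_montage()$labels,
                 annotations = data.frame(onset = 0, duration = n_sec,
                                          label = "burst")),
            class = "eeg_recording")
}

# brute-force Friedman statistic from the rank definition (mid-ranks,
# tie-corrected chi-squared form) -- independent of stats::friedman.test
friedman_bruteforce <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  A <- sum(R^2)
  Cf <- n * k * (k + 1)^2 / 4
  colsums <- colSums(R)
  num <- (k - 1) * sum((colsums - n * (k + 1) / 2)^2)
  den <- A - Cf
  if (den == 0) return(list(statistic = 0, p_value = 1))
  Q <- num / den
  list(statistic = Q, p_value = pchisq(Q, k - 1, lower.tail = FALSE))
}
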