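# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state so that
#' seeded package functions do not disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derivation; keeps results < 2^31.
derive_seed <- function(seed, stream, index = 0L) {
  base <- (as.double(seed) %% 1e6) * 1009 + (stream %% 97) * 101 + index
  as.integer(base %% .Machine$integer.max)
}

# Largest eigenvalue of many Hermitian 3x3 matrices at once.
# M is a complex (or real) array [3, 3, P]; returns numeric length P.
# Analytic trigonometric solution of the characteristic cubic.
eigmax3_batch <- function(M) {
  P <- dim(M)[3]
  d1 <- Re(M[1, 1, ]); d2 <- Re(M[2, 2, ]); d3 <- Re(M[3, 3, ])
  o12 <- M[1, 2, ]; o13 <- M[1, 3, ]; o23 <- M[2, 3, ]
  q <- (d1 + d2 + d3) / 3
  p2 <- 2 * (Mod(o12)^2 + Mod(o13)^2 + Mod(o23)^2) +
    (d1 - q)^2 + (d2 - q)^2 + (d3 - q)^2
  p <- sqrt(pmax(p2, 0) / 6)
  # det(M - qI) of a Hermitian matrix is real
  b11 <- d1 - q; b22 <- d2 - q; b33 <- d3 - q
  detB <- b11 * b22 * b33 +
    2 * Re(o12 * o23 * Conj(o13)) -
    b11 * Mod(o23)^2 - b22 * Mod(o13)^2 - b33 * Mod(o12)^2
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  lam <- q + 2 * p * cos(phi)
  lam[p2 < .Machine$double.eps * pmax(q^2, 1)] <- q[p2 < .Machine$double.eps * pmax(q^2, 1)]
  lam
}

# Batched inverse of complex 3x3 matrices stored as [3, 3, P] (adjugate form).
inv3_batch <- function(G) {
  a <- G[1, 1, ]; b <- G[1, 2, ]; c <- G[1, 3, ]
  d <- G[2, 1, ]; e <- G[2, 2, ]; f <- G[2, 3, ]
  g <- G[3, 1, ]; h <- G[3, 2, ]; i <- G[3, 3, ]
  A <- e * i - f * h; B <- -(d * i - f * g); C <- d * h - e * g
  D <- -(b * i - c * h); E <- a * i - c * g; F <- -(a * h - b * g)
  Gg <- b * f - c * e; H <- -(a * f - c * d); I <- a * e - b * d
  det <- a * A + b * B + c * C
  if (any(Mod(det) < 1e-300))
    stop("singular 3x3 system in batched inverse (grid point ",
         paste(which(Mod(det) < 1e-300), collapse = ", "), ")")
  out <- array(0i, dim(G))
  out[1, 1, ] <- A / det; out[1, 2, ] <- D / det; out[1, 3, ] <- Gg / det
  out[2, 1, ] <- B / det; out[2, 2, ] <- E / det; out[2, 3, ] <- H / det
  out[3, 1, ] <- C / det; out[3, 2, ] <- F / det; out[3, 3, ] <- I / det
  out
}

# Zero-phase Butterworth band-pass (4th-order magnitude response via order-2
# sections run forward and backward).
bandpass_filtfilt <- function(x, fs, band) {
  ny <- fs / 2
  bf <- signal::butter(2, c(band[1] / ny, band[2] / ny), type = "pass")
  if (is.matrix(x)) {
    t(apply(x, 1, function(r) signal::filtfilt(bf, r)))
  } else {
    signal::filtfilt(bf, x)
  }
}

# FIR anti-alias decimation by integer factor using a zero-phase filter.
decimate_fir <- function(x, factor) {
  if (factor == 1) return(x)
  h <- signal::Ma(signal::fir1(128, 0.8 / factor))
  dec1 <- function(r) {
    y <- signal::filtfilt(h, r)
    y[seq(1, length(r), by = factor)]
  }
  if (is.matrix(x)) t(apply(x, 1, dec1)) else dec1(x)
}

# Quantile by linear interpolation between order statistics (documented
# convention for permutation thresholds).
interp_quantile <- function(x, q) {
  as.numeric(stats::quantile(x, probs = q, type = 7, names = FALSE))
}

peak_to_peak <- function(x) {
  if (is.matrix(x)) apply(x, 1, function(r) diff(range(r))) else diff(range(x))
}
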