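# Multitaper spectral estimation on one-second epochs: DPSS tapers,
# auto/cross spectra, pooled power, band-peak detection and the relative
# burst/suppression SNR.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First K DPSS sequences of length n at time-bandwidth product NW, computed
#' from the standard symmetric tridiagonal eigenproblem and orthonormalized.
#' Concentration ratios in the [-W, W] band are attached.
#'
#' @param n Epoch length in samples (>= 8).
#' @param time_bandwidth Time-bandwidth product NW.
#' @param k Number of tapers; must satisfy k <= 2 NW - 1.
#' @return Object of class \code{taper_set}: list with \code{tapers}
#'   (n x k matrix, orthonormal columns), \code{eigenvalues} (concentrations),
#'   \code{n}, \code{nw}, \code{k}.
#' @export
dpss_tapers <- function(n, time_bandwidth = 2, k = 3) {
  n <- as.integer(n)
  if (n < 8) stop("epoch too short for DPSS computation (n >= 8)")
  if (k > 2 * time_bandwidth - 1)
    stop("k = ", k, " tapers exceeds 2*NW - 1 = ", 2 * time_bandwidth - 1)
  key <- paste(n, time_bandwidth, k, sep = "_")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  W <- time_bandwidth / n
  t0 <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  Tm <- matrix(0, n, n)
  Tm[cbind(1:n, 1:n)] <- diag_v
  Tm[cbind(1:(n - 1), 2:n)] <- off_v
  Tm[cbind(2:n, 1:(n - 1))] <- off_v
  eg <- eigen(Tm, symmetric = TRUE)
  H <- eg$vectors[, 1:k, drop = FALSE]
  # orthonormal by construction; fix signs deterministically
  for (j in 1:k) {
    h <- H[, j]
    i <- which.max(abs(h))
    if (h[i] < 0) H[, j] <- -h
    H[, j] <- H[, j] / sqrt(sum(H[, j]^2))
  }
  # band concentration lambda_k = h' S h, S_ij = sin(2 pi W (i-j)) / (pi (i-j))
  d <- outer(t0, t0, "-")
  S <- ifelse(d == 0, 2 * W, sin(2 * pi * W * d) / (pi * d))
  lam <- diag(t(H) %*% S %*% H)
  out <- structure(list(tapers = H, eigenvalues = lam, n = n,
                        nw = time_bandwidth, k = k), class = "taper_set")
  .taper_cache[[key]] <- out
  out
}

# Epoch start indices that do not straddle concatenation joins.
# intervals: list of c(start, end) half-open sample intervals into the
# concatenated data (0-based), as produced by concatenate_phase_segments().
epoch_starts <- function(n_samples, epoch_n, joins = NULL) {
  if (is.null(joins) || length(joins) == 0) {
    bounds <- c(0, n_samples)
  } else {
    bounds <- unique(sort(c(0, joins, n_samples)))
  }
  starts <- integer(0)
  for (i in seq_len(length(bounds) - 1)) {
    len <- bounds[i + 1] - bounds[i]
    ne <- len %/% epoch_n
    if (ne > 0) starts <- c(starts, bounds[i] + (0:(ne - 1)) * epoch_n)
  }
  starts
}

#' Multitaper cross-spectral density
#'
#' Tapers non-overlapping epochs (aligned so that no epoch straddles a
#' concatenation join), Fourier-transforms, and averages the outer products
#' over epochs and tapers.  One-sided density normalization: summing
#' \code{psd * df} over frequencies recovers the tapered-signal variance.
#'
#' @param segments A \code{phase_segments} object, or a channels x samples
#'   matrix (then \code{fs} must be given).
#' @param fs Sampling rate (Hz); taken from \code{segments} if available.
#' @param epoch Epoch length in seconds.
#' @param time_bandwidth,k DPSS parameters.
#' @param keep_epochs Keep the per-epoch tapered Fourier coefficients
#'   (needed by the surrogate permutation machinery).
#' @return Object of class \code{cross_spectrum}: \code{freq} (Hz),
#'   \code{csd} (C x C x nfreq complex, Hermitian per frequency),
#'   \code{psd} (C x nfreq real), \code{n_epochs}, \code{channels},
#'   optionally \code{epoch_fft} (nfreq x C x k x E complex array).
#' @export
multitaper_csd <- function(segments, fs = NULL, epoch = 1,
                           time_bandwidth = 2, k = 3, keep_epochs = FALSE) {
  if (inherits(segments, "phase_segments")) {
    x <- segments$data; fs <- segments$fs; joins <- segments$joins
  } else {
    x <- as.matrix(segments); joins <- NULL
    if (is.null(fs)) stop("fs required when segments is a plain matrix")
  }
  C <- nrow(x)
  N <- round(epoch * fs)
  if (ncol(x) < N) stop("need at least one full epoch of data")
  starts <- epoch_starts(ncol(x), N, joins)
  E <- length(starts)
  if (E < 2)
    warning("fewer than 2 epochs available; single-epoch spectral estimate")
  tp <- dpss_tapers(N, time_bandwidth, k)
  nf <- N %/% 2 + 1
  freq <- (0:(nf - 1)) * fs / N
  X <- array(0i, c(nf, C, k, E))
  for (e in seq_len(E)) {
    seg <- t(x[, (starts[e] + 1):(starts[e] + N), drop = FALSE])  # N x C
    for (j in seq_len(k)) {
      F <- stats::mvfft(seg * tp$tapers[, j])
      X[, , j, e] <- F[1:nf, , drop = FALSE]
    }
  }
  csd <- csd_from_fft(X, fs, N)
  psd <- matrix(0, C, nf)
  for (f in seq_len(nf)) psd[, f] <- Re(diag(matrix(csd[, , f], C, C)))
  labels <- rownames(x) %||% paste0("ch", seq_len(C))
  out <- structure(list(freq = freq, csd = csd, psd = psd,
                        n_epochs = E, fs = fs, epoch = epoch,
                        channels = labels,
                        nw = time_bandwidth, k = k),
                   class = "cross_spectrum")
  if (keep_epochs) out$epoch_fft <- X
  out
}

# CSD array from per-epoch tapered FFT coefficients (nf x C x k x E).
# One-sided density scaling; DC and (even-N) Nyquist bins carry factor 1.
csd_from_fft <- function(X, fs, N) {
  nf <- dim(X)[1]; C <- dim(X)[2]; k <- dim(X)[3]; E <- dim(X)[4]
  csd <- array(0i, c(C, C, nf))
  Xm <- matrix(X, nrow = nf)   # nf x (C*k*E)
  for (f in seq_len(nf)) {
    Z <- matrix(Xm[f, ], nrow = C)        # C x (k*E)
    M <- Z %*% Conj(t(Z)) / (k * E)
    side <- if (f == 1 || (N %% 2 == 0 && f == nf)) 1 else 2
    csd[, , f] <- side * M / fs
  }
  csd
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat("Multitaper cross-spectrum:", length(x$channels), "channels,",
      x$n_epochs, "epochs of", x$epoch, "s,",
      "df =", format(x$freq[2] - x$freq[1]), "Hz\n")
  invisible(x)
}

#' Band-averaged CSD matrix
#'
#' Unweighted mean of the CSD over the integer-frequency bins inside
#' \code{band} (inclusive); the matrix fed to the DICS beamformer.
#'
#' @param cs A \code{cross_spectrum}.
#' @param band Length-2 numeric, Hz.
#' @return C x C complex Hermitian matrix.
#' @export
band_csd <- function(cs, band = c(1, 4)) {
  sel <- which(cs$freq >= band[1] - 1e-9 & cs$freq <= band[2] + 1e-9)
  if (length(sel) == 0) stop("no frequency bins inside the requested band")
  M <- apply(cs$csd[, , sel, drop = FALSE], c(1, 2), mean)
  (M + Conj(t(M))) / 2
}

#' Pooled power spectrum across channels
#'
#' Each channel's spectrum is normalized by its total power, then the
#' normalized spectra are averaged (epoch-count weighting is uniform within
#' one estimate).
#'
#' @param cs A \code{cross_spectrum} (or an object with \code{psd}, \code{freq}).
#' @return List with \code{freq} and \code{power} (unit total power).
#' @export
pooled_power_spectrum <- function(cs) {
  psd <- cs$psd
  if (is.null(psd) || nrow(psd) < 1) stop("empty spectrum set")
  tot <- rowSums(psd)
  if (any(tot <= 0)) tot[tot <= 0] <- 1
  pooled <- colMeans(psd / tot)
  list(freq = cs$freq, power = pooled)
}

#' Locate the dominant frequency band
#'
#' Finds the global maximum of the pooled spectrum inside \code{search} and
#' returns the contiguous frequency band around it where power stays at or
#' above half the maximum, clipped to \code{search}.
#'
#' @param pooled List with \code{freq}, \code{power}.
#' @param search Search range (Hz).
#' @return Numeric c(lo, hi) in Hz.
#' @export
find_band_peak <- function(pooled, search = c(1, 4)) {
  sel <- which(pooled$freq >= search[1] - 1e-9 & pooled$freq <= search[2] + 1e-9)
  if (length(sel) == 0) stop("search range outside spectrum support")
  p <- pooled$power[sel]; f <- pooled$freq[sel]
  if (diff(range(p)) < .Machine$double.eps * max(abs(p), 1)) {
    warning("flat spectrum in search range; returning the full range")
    return(search)
  }
  im <- which.max(p)
  half <- p[im] / 2
  lo <- im; while (lo > 1 && p[lo - 1] >= half) lo <- lo - 1
  hi <- im; while (hi < length(p) && p[hi + 1] >= half) hi <- hi + 1
  c(f[lo], f[hi])
}

#' Relative burst/suppression SNR in dB
#'
#' 10 log10 of the ratio of total band power (summed over channels and
#' in-band frequency bins) of the burst segments to the suppression segments.
#'
#' @param burst,suppression \code{phase_segments} (or matrices with fs).
#' @param band Frequency band (Hz).
#' @param fs Sampling rate if matrices are given.
#' @param ... Passed to \code{multitaper_csd}.
#' @return Scalar dB value.
#' @export
relative_snr_db <- function(burst, suppression, band = c(1, 4), fs = NULL, ...) {
  cb <- multitaper_csd(burst, fs = fs, ...)
  cs <- multitaper_csd(suppression, fs = fs, ...)
  if (!isTRUE(all.equal(cb$fs, cs$fs)) || nrow(cb$psd) != nrow(cs$psd))
    stop("burst and suppression segments must share sampling rate and channels")
  selb <- cb$freq >= band[1] - 1e-9 & cb$freq <= band[2] + 1e-9
  sels <- cs$freq >= band[1] - 1e-9 & cs$freq <= band[2] + 1e-9
  pb <- sum(cb$psd[, selb]); ps <- sum(cs$psd[, sels])
  if (ps <= 0) stop("zero suppression-band power: SNR undefined")
  10 * log10(pb / ps)
}
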