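# Surrogate-based source significance, Friedman phase comparison and
# cohort-level phase contrasts.

#' Surrogate significance for coherent sources
#'
#' Monte-Carlo permutation null for off-reference source coherence.  Each
#' permutation shuffles the order of the one-second epochs of the extracted
#' reference signal relative to all grid signals (destroying temporal
#' alignment while preserving every spectrum) and recomputes the
#' reference-to-grid band statistic from the cached tapered Fourier
#' coefficients through the observed (fixed) spatial filters.
#'
#' Because beamformer outputs share sensors, their plain coherence contains
#' an instantaneous volume-conduction overlap that no misalignment null can
#' reproduce; significance is therefore assessed on the imaginary part of
#' coherency, which is zero in expectation under instantaneous mixing and
#' so is comparable between the observed data and the shuffled null (and
#' valid on genuinely source-free data).  The generator's couplings are
#' lagged (31-62 ms), so true coupling carries a substantial imaginary
#' component.  The family-wise threshold is the \code{quantile_p} quantile
#' (linear interpolation) of the null distribution of the maximum imaginary
#' coherence outside the reference's exclusion sphere.
#'
#' @param segments A \code{phase_segments} object.
#' @param leadfield A \code{lead_field}.
#' @param lambda Beamformer regularization fraction for the coherence map.
#' @param lambda_ref Regularization for the reference-selection power map.
#' @param n_perm Number of permutations (>= 20).
#' @param quantile_p Null quantile defining the threshold.
#' @param band Analysis band (Hz).
#' @param exclusion_mm Exclusion radius around the reference.
#' @param seed RNG seed.
#' @param epoch,time_bandwidth,k Multitaper parameters.
#' @return Object of class \code{surrogate_distribution}: \code{null}
#'   (per-permutation off-reference coherence maxima), \code{threshold},
#'   \code{observed} (the observed off-reference maximum), \code{p_value},
#'   plus the observed \code{power_map}, \code{coherence_map} and reference.
#' @export
surrogate_source_threshold <- function(segments, leadfield, lambda = 0.05,
                                       lambda_ref = 0.5,
                                       n_perm = 100, quantile_p = 0.99,
                                       band = c(1, 4), exclusion_mm = 20,
                                       seed = NULL, epoch = 1,
                                       time_bandwidth = 2, k = 3) {
  if (n_perm < 20) stop("n_perm must be at least 20 for a stable quantile")
  cs <- multitaper_csd(segments, epoch = epoch, time_bandwidth = time_bandwidth,
                       k = k, keep_epochs = TRUE)
  if (cs$n_epochs < 10) stop("need at least 10 one-second epochs")
  Cobs <- band_csd(cs, band)
  # reference from the strongly regularized map (robust to the partial
  # self-cancellation a correlated network hub suffers under minimum
  # variance); coherence mapping through weakly regularized (sharp) filters
  ref <- select_reference(source_power_map(Cobs, leadfield, lambda_ref, band))
  pm <- source_power_map(Cobs, leadfield, lambda, band)
  pts <- pm$grid$points
  dref <- sqrt(rowSums(sweep(pts, 2, pts[ref, ], "-")^2))
  off <- dref > exclusion_mm
  cm <- source_coherence_map(pm, ref)
  sel <- which(cs$freq >= band[1] - 1e-9 & cs$freq <= band[2] + 1e-9)
  X <- cs$epoch_fft[sel, , , , drop = FALSE]   # nb x C x k x E
  nb <- length(sel); C <- dim(X)[2]; K <- dim(X)[3]; E <- dim(X)[4]
  P <- nrow(pts)
  a <- pm$a                                    # fixed scalar filters, E x P
  Xm <- matrix(aperm(X, c(2, 1, 3, 4)), nrow = C)     # C x (nb K E)
  S <- crossprod(Conj(a), Xm)                         # P x (nb K E)
  Sv <- array(S, c(P, nb, K, E))
  Sref <- Sv[ref, , , , drop = TRUE]                  # nb x K x E
  pw <- rowMeans(Mod(Sv)^2)
  Svm <- matrix(Sv, nrow = P)
  cross_obs <- drop(Svm %*% Conj(as.vector(Sref))) / (nb * K * E)
  icoh <- Im(cross_obs)^2 / (pw * pw[ref])
  icoh[ref] <- 0
  null <- numeric(n_perm)
  with_seed(seed, {
    for (q in seq_len(n_perm)) {
      perm <- sample.int(E)
      Sr <- Sref[, , perm, drop = FALSE]
      cross <- drop(Svm %*% Conj(as.vector(Sr))) / (nb * K * E)
      icq <- Im(cross)^2 / (pw * pw[ref])
      null[q] <- max(icq[off], na.rm = TRUE)
    }
  })
  observed <- max(icoh[off])
  thr <- interp_quantile(null, quantile_p)
  pval <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(statistic = "max off-reference imaginary source coherence",
                 n_perm = n_perm, null = null, threshold = thr,
                 observed = observed, p_value = pval,
                 quantile = quantile_p, imag_coherence = icoh,
                 power_map = pm, reference = ref, coherence_map = cm),
            class = "surrogate_distribution")
}

#' @export
print.surrogate_distribution <- function(x, ...) {
  cat(sprintf("Surrogate null (%s): %d permutations\n", x$statistic, x$n_perm))
  cat(sprintf("  threshold (q%.2f) = %.3f, observed = %.3f, p = %.4f\n",
              x$quantile, x$threshold, x$observed, x$p_value))
  invisible(x)
}

#' Friedman rank test across paired conditions
#'
#' Rank-based two-way analysis of variance on a subjects x conditions matrix
#' (mid-ranks for ties; chi-squared reference with k - 1 degrees of freedom).
#' Degenerate input with every row constant returns statistic 0, p = 1.
#'
#' @param mat Subjects x conditions numeric matrix.
#' @return List with \code{statistic}, \code{p_value}, \code{df}.
#' @export
friedman_phase_test <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need at least 2 subjects and 2 conditions")
  if (all(apply(mat, 1, function(r) diff(range(r)) == 0)))
    return(list(statistic = 0, p_value = 1, df = ncol(mat) - 1L))
  ft <- stats::friedman.test(mat)
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       df = unname(ft$parameter))
}

#' Burst-versus-suppression cohort contrast
#'
#' Collects per-subject mean source power and mean pairwise source coherence
#' for each phase and tests the paired difference with the Friedman test.
#' Subjects missing a phase are excluded (with a message).
#'
#' @param subject_results List of per-subject results from
#'   \code{\link{run_subject}}.
#' @return Object of class \code{phase_contrast}: matrices \code{power} and
#'   \code{coherence} (subjects x phases), the two Friedman results and the
#'   direction of each difference.
#' @export
compare_phases <- function(subject_results) {
  keep <- vapply(subject_results, function(s)
    !is.null(s$phases$burst) && !is.null(s$phases$suppression), TRUE)
  if (any(!keep))
    message(sum(!keep), " subject(s) missing a phase; excluded from contrast")
  sr <- subject_results[keep]
  if (length(sr) < 2) stop("need at least 2 complete subjects")
  getm <- function(s, phase, what) s$phases[[phase]][[what]]
  pw <- cbind(burst = vapply(sr, getm, 1, phase = "burst", what = "mean_source_power"),
              suppression = vapply(sr, getm, 1, phase = "suppression",
                                   what = "mean_source_power"))
  ch <- cbind(burst = vapply(sr, getm, 1, phase = "burst", what = "mean_source_coherence"),
              suppression = vapply(sr, getm, 1, phase = "suppression",
                                   what = "mean_source_coherence"))
  fp <- friedman_phase_test(pw)
  fc <- friedman_phase_test(ch)
  structure(list(power = pw, coherence = ch,
                 power_test = fp, coherence_test = fc,
                 power_direction = ifelse(mean(pw[, 1] - pw[, 2]) > 0,
                                          "burst > suppression",
                                          "suppression > burst"),
                 coherence_direction = ifelse(mean(ch[, 1] - ch[, 2]) > 0,
                                              "burst > suppression",
                                              "suppression > burst")),
            class = "phase_contrast")
}

#' @export
print.phase_contrast <- function(x, ...) {
  cat("Phase contrast over", nrow(x$power), "subjects\n")
  cat(sprintf("  source power:    %s (Friedman Q = %.2f, p = %.2g)\n",
              x$power_direction, x$power_test$statistic, x$power_test$p_value))
  cat(sprintf("  mean coherence:  %s (Friedman Q = %.2f, p = %.2g)\n",
              x$coherence_direction, x$coherence_test$statistic,
              x$coherence_test$p_value))
  invisible(x)
}
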