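# DICS frequency-domain beamformer: spatial filters, source power and
# coherence maps, automated coherent-source iteration, and source-signal
# extraction.
#
# Filter construction per grid point r with leadfield L (E x 3):
#   A(r) = (L' Creg^-1 L)^-1 L' Creg^-1,  Creg = C + lambda * (tr C / E) * I
# The unit-gain constraint A L = I3 holds by construction.  Per point we keep
# two scalars: the noise-normalized power (neural activity index, the
# generalized eigenvalue of Re(A C A^H) against the weight matrix Re(A A^H)),
# which is depth-unbiased and drives localization and reference selection,
# and the raw band power along the NAI orientation u, P = Re(a' C a) with
# a = A' u, which normalizes coherence.  Reference-to-grid coherence is the
# scalar |a_ref' C a_r|^2 / (P_ref P_r), bounded by 1 via Cauchy-Schwarz.

dics_regularize <- function(C, lambda) {
  E <- nrow(C)
  C + lambda * (sum(Re(diag(C))) / E) * diag(E)
}

# Batched filters for all grid points: A [3, E, P].
dics_filters_batch <- function(C, gain, lambda) {
  E <- dim(gain)[1]; P <- dim(gain)[2]
  Creg <- dics_regularize(C, lambda)
  Ci <- solve(Creg)
  L <- aperm(gain, c(1, 3, 2))                   # E x 3 x P
  Lmat <- matrix(L, nrow = E)                    # E x (3P)
  Tarr <- array(Ci %*% Lmat, c(E, 3, P))         # Ci L
  G <- array(0i, c(3, 3, P))
  for (i in 1:3) for (j in 1:3)
    G[i, j, ] <- colSums(L[, i, , drop = FALSE] * Tarr[, j, , drop = FALSE],
                         dims = 1)
  Ginv <- inv3_batch(G)
  A <- array(0i, c(3, E, P))
  CT <- Conj(Tarr)                               # Conj(Ci L) -> (L' Ci)'
  for (i in 1:3) {
    acc <- matrix(0i, E, P)
    for (j in 1:3)
      acc <- acc + sweep(CT[, j, , drop = TRUE], 2, Ginv[i, j, ], "*")
    A[i, , ] <- acc
  }
  A
}

# Batched M_p = A_p X A_p^H for all points ([3,3,P] complex), X an E x E matrix.
dics_quadform_batch <- function(A, X) {
  E <- dim(A)[2]; P <- dim(A)[3]
  B <- array(0i, c(3, E, P))
  for (i in 1:3) B[i, , ] <- t(t(A[i, , ]) %*% X)
  M <- array(0i, c(3, 3, P))
  CA <- Conj(A)
  for (i in 1:3) for (j in 1:3)
    M[i, j, ] <- colSums(B[i, , , drop = TRUE] * CA[j, , , drop = TRUE])
  M
}

sym3 <- function(M) {
  H <- array(0, dim(M)); H[] <- Re(M)
  for (i in 1:3) for (j in 1:3) if (i < j) {
    s <- (H[i, j, ] + H[j, i, ]) / 2; H[i, j, ] <- s; H[j, i, ] <- s
  }
  H
}

# Largest real eigenvalue of general real 3x3 matrices [3,3,P] whose spectrum
# is known to be real (here W^-1 H with W > 0, H symmetric): solve the
# characteristic cubic trigonometrically.
eigmax3_general_batch <- function(M) {
  c2 <- M[1, 1, ] + M[2, 2, ] + M[3, 3, ]
  c1 <- (M[1, 1, ] * M[2, 2, ] - M[1, 2, ] * M[2, 1, ]) +
    (M[1, 1, ] * M[3, 3, ] - M[1, 3, ] * M[3, 1, ]) +
    (M[2, 2, ] * M[3, 3, ] - M[2, 3, ] * M[3, 2, ])
  c0 <- M[1, 1, ] * (M[2, 2, ] * M[3, 3, ] - M[2, 3, ] * M[3, 2, ]) -
    M[1, 2, ] * (M[2, 1, ] * M[3, 3, ] - M[2, 3, ] * M[3, 1, ]) +
    M[1, 3, ] * (M[2, 1, ] * M[3, 2, ] - M[2, 2, ] * M[3, 1, ])
  p <- c1 - c2^2 / 3
  q <- 2 * c2^3 / 27 - c2 * c1 / 3 + c0
  disc <- pmax(-p / 3, 0)
  r <- sqrt(disc)
  arg <- ifelse(r > 0, 3 * q / (2 * p * r), 0)
  arg <- pmin(pmax(-arg, -1), 1)
  lam <- ifelse(r > 0, 2 * r * cos(acos(arg) / 3), 0) + c2 / 3
  lam
}

# Eigenvector for a given eigenvalue of real 3x3 matrices (batched): any
# non-trivial column of adj(M - lam I); pick the largest, normalize, fix sign.
eigvec3_batch <- function(M, lam) {
  P <- dim(M)[3]
  B <- M
  for (i in 1:3) B[i, i, ] <- M[i, i, ] - lam
  adj <- array(0, c(3, 3, P))
  idx <- list(c(2, 3), c(1, 3), c(1, 2))
  for (i in 1:3) for (j in 1:3) {
    r <- idx[[j]]; c0 <- idx[[i]]
    adj[i, j, ] <- (-1)^(i + j) *
      (B[r[1], c0[1], ] * B[r[2], c0[2], ] - B[r[1], c0[2], ] * B[r[2], c0[1], ])
  }
  n2 <- apply(adj^2, c(2, 3), sum)               # column norms^2 [3, P]
  pick <- max.col(t(n2), ties.method = "first")
  V <- matrix(0, 3, P)
  for (j in 1:3) {
    sel <- pick == j
    if (any(sel)) V[, sel] <- adj[, j, sel]
  }
  nv <- sqrt(colSums(V^2))
  bad <- nv < 1e-30
  if (any(bad)) { V[1, bad] <- 1; nv[bad] <- 1 }
  V <- V / rep(nv, each = 3)
  flip <- V[max.col(t(abs(V)), ties.method = "first") + 3 * (seq_len(P) - 1)] < 0
  V[, flip] <- -V[, flip]
  V
}

# Radial scalar engine: one filter per voxel from the radially-oriented
# leadfield column, a = Ci l / (l' Ci l).  NAI is the unit-noise-gain
# normalized power P / ||a||^2.
dics_radial_engine <- function(C, gain, points, lambda) {
  E <- dim(gain)[1]; P <- dim(gain)[2]
  r <- sqrt(rowSums(points^2))
  U <- points / ifelse(r > 1e-6, r, 1)
  U[r <= 1e-6, ] <- rep(c(0, 0, 1), each = sum(r <= 1e-6))
  l <- matrix(0, E, P)
  for (o in 1:3) l <- l + gain[, , o] * rep(U[, o], each = E)
  Creg <- dics_regularize(C, lambda)
  Ci <- solve(Creg)
  Cl <- Ci %*% l                                # E x P
  den <- colSums(l * Cl)                        # l' Ci l (real for Hermitian Ci)
  den <- Re(den)
  if (any(abs(den) < 1e-300))
    stop("singular l' Creg^-1 l at grid point ",
         which(abs(den) < 1e-300)[1])
  a <- sweep(Cl, 2, den, "/")
  pw <- Re(colSums(Conj(a) * (C %*% a)))
  nai <- pw / pmax(Re(colSums(Mod(a)^2)), 1e-300)
  list(a = a, nai = pmax(nai, 0), power = pmax(pw, 0), orientations = U)
}

# Free-orientation engine (vector filters reduced by the generalized
# power-vs-weight eigenproblem).
# Returns scalar filters a [E, P], nai, power, orientations [P, 3].
dics_scalar_engine <- function(C, gain, lambda) {
  A <- dics_filters_batch(C, gain, lambda)
  H <- sym3(dics_quadform_batch(A, C))
  E <- dim(A)[2]; P <- dim(A)[3]
  W <- array(0, c(3, 3, P))
  for (i in 1:3) for (j in 1:3)
    W[i, j, ] <- Re(colSums(A[i, , , drop = TRUE] * Conj(A[j, , , drop = TRUE])))
  Winv <- array(0, c(3, 3, P))
  Winv[] <- Re(inv3_batch(W + 0i))
  M <- array(0, c(3, 3, P))
  for (i in 1:3) for (j in 1:3) {
    acc <- numeric(P)
    for (k in 1:3) acc <- acc + Winv[i, k, ] * H[k, j, ]
    M[i, j, ] <- acc
  }
  nai <- eigmax3_general_batch(M)
  U <- eigvec3_batch(M, nai)                     # 3 x P
  a <- matrix(0i, E, P)
  for (i in 1:3) a <- a + A[i, , , drop = TRUE] * rep(U[i, ], each = E)
  pw <- Re(colSums(Conj(a) * (C %*% a)))
  list(a = a, nai = pmax(nai, 0), power = pmax(pw, 0), orientations = t(U),
       A = A)
}

#' DICS spatial filter at one location
#'
#' @param C Band-averaged CSD matrix (E x E, Hermitian).
#' @param leadfield_r E x 3 gain matrix at the target location.
#' @param lambda Regularization as a fraction of mean sensor power.
#' @return Object of class \code{spatial_filter}: \code{A} (3 x E complex;
#'   unit gain A L = I), \code{lambda}, plus the real-valued extraction
#'   filter \code{A_real} computed from Re(Creg).
#' @export
dics_spatial_filter <- function(C, leadfield_r, lambda = 0.05) {
  L <- as.matrix(leadfield_r)
  Creg <- dics_regularize(C, lambda)
  Ci <- solve(Creg)
  G <- t(L) %*% Ci %*% L
  if (rcond(Re(G)) < 1e-14)
    stop("singular L' Creg^-1 L at the requested location")
  A <- solve(G, t(L) %*% Ci)
  Cr <- Re(Creg)
  Cri <- solve(Cr)
  Ar <- solve(t(L) %*% Cri %*% L, t(L) %*% Cri)
  structure(list(A = A, A_real = Ar, lambda = lambda, leadfield = L),
            class = "spatial_filter")
}

#' Source power map
#'
#' Beamformer band power at every grid point.  Two per-point scalars are
#' returned: \code{power}, the raw band power of the scalar beamformer
#' output, used for coherence normalization and absolute-power summaries,
#' and \code{nai}, its noise-normalized (unit-noise-gain) counterpart used
#' for localization and reference selection, which removes the depth bias of
#' raw minimum-variance power.
#'
#' With \code{orientation = "radial"} (default) each grid point uses the
#' radially-oriented leadfield column — the classical scalar beamformer for
#' spherical volume conductors, whose topographies separate far better at
#' 19 electrodes than free orientations.  \code{"free"} estimates the
#' orientation per point from the generalized power-versus-weight
#' eigenproblem.
#'
#' @param C Band CSD matrix (from \code{\link{band_csd}}), or a
#'   \code{cross_spectrum} (then \code{band} selects bins).
#' @param leadfield A \code{lead_field}.
#' @param lambda Regularization fraction.
#' @param band Band in Hz when \code{C} is a \code{cross_spectrum}.
#' @param orientation "radial" or "free".
#' @return Object of class \code{power_map}: \code{nai}, \code{power},
#'   \code{orientations} (P x 3), scalar filters \code{a} (E x P complex),
#'   \code{grid}, \code{lambda}, \code{band}, \code{csd}.
#' @export
source_power_map <- function(C, leadfield, lambda = 0.05, band = c(1, 4),
                             orientation = c("radial", "free")) {
  orientation <- match.arg(orientation)
  if (inherits(C, "cross_spectrum")) C <- band_csd(C, band)
  eng <- if (orientation == "radial")
    dics_radial_engine(C, leadfield$gain, leadfield$grid$points, lambda)
  else dics_scalar_engine(C, leadfield$gain, lambda)
  structure(list(nai = eng$nai, power = eng$power,
                 orientations = eng$orientations, a = eng$a,
                 grid = leadfield$grid, lambda = lambda, band = band,
                 orientation = orientation,
                 csd = C),
            class = "power_map")
}

#' @export
print.power_map <- function(x, ...) {
  cat("DICS power map:", length(x$power), "grid points; NAI max at (",
      paste(x$grid$points[which.max(x$nai), ], collapse = ", "), ") mm\n")
  invisible(x)
}

#' Reference region: the power-map maximum
#'
#' The grid point maximizing the noise-normalized power.  Deterministic
#' tie-break: the lowest grid index among exact maxima.
#'
#' @param pm A \code{power_map}.
#' @return Grid point index (integer) with attribute \code{location}.
#' @export
select_reference <- function(pm) {
  if (length(pm$nai) == 0) stop("empty power map")
  i <- which(pm$nai == max(pm$nai))[1]
  structure(i, location = pm$grid$points[i, ])
}

#' Coherence map against a reference grid point
#'
#' Magnitude-squared coherence between the reference and every grid point on
#' the band CSD through the scalar beamformer filters:
#' coh(r) = |a_ref' C a_r|^2 / (P_ref P_r).  Values are clamped to [0, 1]
#' (the scalar reduction is Cauchy-Schwarz-bounded, so clamping only absorbs
#' rounding); the reference's own value is 1 by definition.
#'
#' @param pm A \code{power_map} (carries the filters and CSD).
#' @param reference Grid index from \code{\link{select_reference}}.
#' @return Object of class \code{coherence_map}: \code{coherence},
#'   \code{reference}, \code{grid}, \code{n_clamped}.
#' @export
source_coherence_map <- function(pm, reference) {
  ref <- as.integer(reference)
  P <- ncol(pm$a)
  if (ref < 1 || ref > P) stop("reference index outside the grid")
  r <- Conj(pm$a[, ref]) %*% pm$csd              # 1 x E
  num <- Mod(drop(r %*% pm$a))^2
  pw <- pm$power
  coh <- numeric(P)
  ok <- pw > 0 & pw[ref] > 0
  coh[ok] <- num[ok] / (pw[ref] * pw[ok])
  n_clamped <- sum(coh > 1 + 1e-12)
  coh <- pmin(pmax(coh, 0), 1)
  coh[ref] <- 1
  structure(list(coherence = coh, reference = ref, grid = pm$grid,
                 n_clamped = n_clamped),
            class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat("DICS coherence map: reference point", x$reference, "at (",
      paste(x$grid$points[x$reference, ], collapse = ", "), ") mm\n")
  invisible(x)
}

# Indices of local maxima of the NAI map (neighborhood 1.5 x grid spacing).
nai_local_maxima <- function(pm) {
  pts <- pm$grid$points
  v <- pm$nai
  r2 <- (1.5 * pm$grid$spacing)^2
  P <- nrow(pts)
  out <- logical(P)
  for (i in seq_len(P)) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 +
      (pts[, 3] - pts[i, 3])^2
    nb <- d2 <= r2 & d2 > 0
    out[i] <- all(v[i] >= v[nb])
  }
  which(out)
}

#' Automated coherent-source identification
#'
#' Greedy loop mirroring the automated reference/coherent-source selection:
#' the reference is the power-map maximum; further sources are successive
#' maxima of the reference coherence map outside exclusion spheres around all
#' previously found sources, until no candidate remains significant or
#' \code{max_sources} are found.
#'
#' Candidate locations are the local maxima of the noise-normalized power
#' map (distinct activity peaks); each candidate must be significantly
#' coherent with the reference -- with a \code{surrogate_distribution}, its
#' imaginary coherence must exceed the family-wise surrogate threshold;
#' with a plain numeric \code{threshold}, its coherence must exceed it.
#' Significant candidates are accepted in decreasing coherence order,
#' subject to exclusion spheres around already accepted sources.
#'
#' @param pm A \code{power_map}.
#' @param threshold Numeric coherence cutoff or \code{surrogate_distribution}
#'   from \code{\link{surrogate_source_threshold}}.
#' @param exclusion_mm Exclusion sphere radius around found sources.
#' @param max_sources Cap on the total number of sources (including the
#'   reference).
#' @param reference Optional grid index overriding power-map reference
#'   selection (used by the pipeline's strongly-regularized reference step).
#' @return Object of class \code{coherent_sources}: data frame \code{sources}
#'   (index, x, y, z, role, statistic, coherence), the coherence map, and the
#'   orientations of the selected points.
#' @export
iterate_coherent_sources <- function(pm, threshold, exclusion_mm = 20,
                                     max_sources = 8, reference = NULL) {
  if (is.null(reference) && inherits(threshold, "surrogate_distribution"))
    reference <- threshold$reference
  ref <- if (is.null(reference)) select_reference(pm) else as.integer(reference)
  cm <- source_coherence_map(pm, ref)
  pts <- pm$grid$points
  cand <- nai_local_maxima(pm)
  cand <- setdiff(cand, ref)
  if (inherits(threshold, "surrogate_distribution")) {
    cand <- cand[threshold$imag_coherence[cand] >= threshold$threshold]
  } else {
    cand <- cand[cm$coherence[cand] >= threshold]
  }
  cand <- cand[order(cm$coherence[cand], decreasing = TRUE)]
  found <- data.frame(index = as.integer(ref),
                      x = pts[ref, 1], y = pts[ref, 2], z = pts[ref, 3],
                      role = "reference", statistic = pm$nai[ref],
                      coherence = 1,
                      stringsAsFactors = FALSE)
  for (i in cand) {
    if (nrow(found) >= max_sources) break
    dmin <- min(sqrt(rowSums(sweep(as.matrix(found[, c("x", "y", "z")]), 2,
                                   pts[i, ], "-")^2)))
    if (dmin <= exclusion_mm) next
    found <- rbind(found, data.frame(index = as.integer(i),
                                     x = pts[i, 1], y = pts[i, 2], z = pts[i, 3],
                                     role = "coherent",
                                     statistic = pm$nai[i],
                                     coherence = cm$coherence[i],
                                     stringsAsFactors = FALSE))
  }
  idx <- found$index
  structure(list(sources = found,
                 coherence_map = cm,
                 power_map = pm,
                 orientations = pm$orientations[idx, , drop = FALSE],
                 threshold = if (is.numeric(threshold)) threshold
                 else threshold$threshold,
                 exclusion_mm = exclusion_mm),
            class = "coherent_sources")
}

#' @export
print.coherent_sources <- function(x, ...) {
  cat("Coherent source set:", nrow(x$sources), "sources",
      sprintf("(threshold %.3f)\n", x$threshold))
  print(x$sources[, c("role", "x", "y", "z", "statistic", "coherence")],
        row.names = FALSE)
  invisible(x)
}

#' Extract source signals with the spatial filters
#'
#' For each identified source, applies the real-valued unit-gain beamformer
#' along the stored dominant orientation: s_i(t) = u_i' A_i x(t).  The filter
#' sign is canonicalized so its first non-negligible coefficient is positive.
#'
#' @param sensor_data Channels x samples matrix, band-filtered to the
#'   analysis band and average-referenced.
#' @param source_set A \code{coherent_sources} object.
#' @param leadfield The \code{lead_field} used for the maps.
#' @param lambda Regularization fraction.
#' @return Sources x samples matrix; row names carry the source roles.
#' @export
extract_source_signals <- function(sensor_data, source_set, leadfield,
                                   lambda = 0.05) {
  x <- as.matrix(sensor_data)
  E <- dim(leadfield$gain)[1]
  if (nrow(x) != E) stop("sensor data has ", nrow(x),
                         " channels but the leadfield has ", E)
  idx <- source_set$sources$index
  Creal <- Re(source_set$power_map$csd)
  out <- matrix(0, length(idx), ncol(x))
  for (s in seq_along(idx)) {
    L <- leadfield$gain[, idx[s], ]
    flt <- dics_spatial_filter(Creal, L, lambda)
    u <- source_set$orientations[s, ]
    w <- drop(u %*% flt$A_real)
    i0 <- which(abs(w) > 1e-12 * max(abs(w)))[1]
    if (!is.na(i0) && w[i0] < 0) w <- -w
    out[s, ] <- drop(w %*% x)
  }
  rownames(out) <- make.unique(source_set$sources$role)
  out
}
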