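# Analytic EEG forward model: five concentric spherical shells, dipole
# sources, Legendre-series solution with adaptive truncation.
#
# Geometry and units: origin at the sphere centre, +x right, +y anterior,
# +z superior; distances mm, conductivities S/m, dipole moments nA*m,
# potentials microvolts.

#' Five-shell concentric-spheres volume conductor
#'
#' Validates shell radii and conductivities and precomputes the per-degree
#' radial transfer coefficients used by the series forward solution.  Shells
#' are ordered innermost to outermost and correspond anatomically to white
#' matter, grey matter, CSF, skull and scalp.  The defaults are infant-scaled:
#' a 70 mm scalp sphere with a comparatively conductive neonatal skull.
#'
#' @param radii Five strictly increasing shell radii (mm).
#' @param conductivities Five strictly positive conductivities (S/m),
#'   innermost first.
#' @param max_terms Hard cap on the Legendre series degree.
#' @return An object of class \code{sphere_model}.
#' @examples
#' mod <- build_sphere_model()
#' mod$radii
#' @export
build_sphere_model <- function(radii = c(58, 60, 62, 65, 70),
                               conductivities = c(0.33, 0.33, 1.79, 0.04, 0.33),
                               max_terms = 200L) {
  radii <- as.numeric(radii); conductivities <- as.numeric(conductivities)
  if (length(radii) != 5L || length(conductivities) != 5L)
    stop("a five-shell model requires exactly 5 radii and 5 conductivities")
  if (any(diff(radii) <= 0))
    stop("shell radii must be strictly increasing")
  if (any(conductivities <= 0))
    stop("shell conductivities must be strictly positive")
  m <- structure(list(radii = radii, conductivities = conductivities,
                      max_terms = as.integer(max_terms)),
                 class = "sphere_model")
  m$transfer <- shell_transfer_coefficients(radii, conductivities, max_terms)
  m
}

#' @export
print.sphere_model <- function(x, ...) {
  cat("Concentric-spheres head model (5 shells)\n")
  cat("  radii (mm):        ", paste(format(x$radii), collapse = ", "), "\n")
  cat("  conductivity (S/m):", paste(format(x$conductivities), collapse = ", "), "\n")
  invisible(x)
}

# Per-degree scalp transfer coefficients tau_n.
#
# For each Legendre degree n the potential in shell j is
# a_j (r/r_j)^n + b_j (r_{j-1}/r)^{n+1}; the dipole's primary field in the
# innermost region is written as (r_1/r)^{n+1} with unit coefficient.
# Continuity of potential and radial current at the four interfaces plus the
# insulating outer boundary give a 9x9 linear system per degree; tau_n is the
# resulting total potential at the scalp surface per unit primary coefficient.
# The scaled basis keeps every matrix entry O(1) up to degree 200.
shell_transfer_coefficients <- function(radii, cond, nmax) {
  ns <- length(radii)
  tau <- numeric(nmax)
  for (n in seq_len(nmax)) {
    # unknown order: a_1, then (a_j, b_j) for j = 2..ns
    nu <- 2 * ns - 1
    Amat <- matrix(0, nu, nu)
    rhs <- numeric(nu)
    idx_a <- function(j) if (j == 1) 1L else 2L * (j - 1L)
    idx_b <- function(j) 2L * (j - 1L) + 1L
    row <- 0L
    for (j in seq_len(ns - 1)) {
      r <- radii[j]
      # value continuity at interface j
      row <- row + 1L
      Amat[row, idx_a(j)] <- 1
      if (j > 1) Amat[row, idx_b(j)] <- (radii[j - 1] / r)^(n + 1)
      Amat[row, idx_a(j + 1)] <- -(r / radii[j + 1])^n
      Amat[row, idx_b(j + 1)] <- -1
      if (j == 1) rhs[row] <- -1          # primary (r1/r)^(n+1) at r = r1
      # radial current continuity at interface j
      row <- row + 1L
      Amat[row, idx_a(j)] <- cond[j] * n / r
      if (j > 1) Amat[row, idx_b(j)] <- -cond[j] * (n + 1) / r * (radii[j - 1] / r)^(n + 1)
      Amat[row, idx_a(j + 1)] <- -cond[j + 1] * n / r * (r / radii[j + 1])^n
      Amat[row, idx_b(j + 1)] <- cond[j + 1] * (n + 1) / r
      if (j == 1) rhs[row] <- cond[1] * (n + 1) / r
    }
    # insulating outer boundary at r = r_ns
    row <- row + 1L
    r <- radii[ns]
    Amat[row, idx_a(ns)] <- n / r
    Amat[row, idx_b(ns)] <- -(n + 1) / r * (radii[ns - 1] / r)^(n + 1)
    sol <- solve(Amat, rhs)
    tau[n] <- sol[idx_a(ns)] + sol[idx_b(ns)] * (radii[ns - 1] / radii[ns])^(n + 1)
  }
  tau
}

#' Regular source grid inside the innermost shell
#'
#' Cubic lattice (including the origin) clipped so that every point satisfies
#' |r| < r_inner - spacing/2.
#'
#' @param model A \code{sphere_model}.
#' @param spacing Lattice step in mm.
#' @return Object of class \code{source_grid}: list with \code{points}
#'   (P x 3 matrix, mm) and \code{spacing}.
#' @export
build_source_grid <- function(model, spacing = 10) {
  r1 <- model$radii[1]
  if (spacing <= 0 || spacing >= r1)
    stop("grid spacing must be in (0, ", r1, ") mm")
  k <- floor(r1 / spacing)
  ax <- spacing * (-k:k)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  keep <- sqrt(rowSums(pts^2)) < r1 - spacing / 2
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0)
    stop("grid spacing ", spacing, " mm leaves no points inside the innermost shell")
  rownames(pts) <- NULL
  structure(list(points = pts, spacing = spacing), class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat("Source grid:", nrow(x$points), "points at", x$spacing, "mm spacing\n")
  invisible(x)
}

# Angular series sums for one dipole location against all electrodes.
# Returns S_rad (per electrode), S_tan, cos_alpha, that and the tangential
# unit vectors needed to assemble potentials for any moment.
forward_series <- function(model, elec_dir, b_frac, n_terms, tol = 1e-8) {
  tau <- model$transfer
  nmax <- min(n_terms, length(tau))
  x <- elec_dir$cosa
  ne <- length(x)
  Pnm1 <- rep(1, ne)          # P_0
  Pn <- x                      # P_1
  s <- sqrt(pmax(1 - x^2, 0))
  P1nm1 <- rep(0, ne)          # P_0^1
  P1n <- s                     # P_1^1
  f <- b_frac
  fpow <- 1                    # f^(n-1)
  Srad <- tau[1] * 1 * Pn      # n * P_n with n = 1
  Stan <- tau[1] * P1n
  if (nmax >= 2) {
    for (n in 2:nmax) {
      Pn1 <- ((2 * n - 1) * x * Pn - (n - 1) * Pnm1) / n
      P1n1 <- if (n == 2) 3 * x * s else
        ((2 * n - 1) * x * P1n - n * P1nm1) / (n - 1)
      Pnm1 <- Pn; Pn <- Pn1
      P1nm1 <- P1n; P1n <- P1n1
      fpow <- fpow * f
      tr <- tau[n] * fpow * n * Pn
      tt <- tau[n] * fpow * P1n
      Srad <- Srad + tr
      Stan <- Stan + tt
      scale_now <- max(max(abs(Srad)), max(abs(Stan)), 1e-300)
      if (max(max(abs(tr)), max(abs(tt))) < tol * scale_now) break
    }
  }
  list(Srad = Srad, Stan = Stan)
}

# Electrode geometry relative to a dipole axis zhat.
elec_geometry <- function(positions, zhat) {
  R <- sqrt(rowSums(positions^2))
  e <- positions / R
  cosa <- pmin(pmax(drop(e %*% zhat), -1), 1)
  tvec <- e - outer(cosa, zhat)
  tn <- sqrt(rowSums(tvec^2))
  sina <- sqrt(pmax(1 - cosa^2, 0))
  # that * sin(alpha): the tangential angular factor P_n^1 already carries
  # sin(alpha), so we need the unit tangential direction; where sin ~ 0 the
  # tangential term vanishes and the direction is immaterial.
  that <- tvec
  ok <- tn > 1e-12
  that[ok, ] <- tvec[ok, , drop = FALSE] / tn[ok]
  that[!ok, ] <- 0
  list(cosa = cosa, sina = sina, that = that)
}

#' Scalp potentials of a current dipole in the shell model
#'
#' Series solution for a dipole strictly inside the innermost shell.  The
#' series is truncated adaptively once the last term contributes less than
#' \code{tol} relative to the running sum, or at \code{n_terms}.
#' Potentials are returned average-referenced.
#'
#' @param model A \code{sphere_model}.
#' @param montage An \code{electrode_montage} on the outermost shell.
#' @param location Dipole position, 3-vector (mm).
#' @param moment Dipole moment, 3-vector (nA m).
#' @param n_terms Maximum series degree.
#' @param average_reference Subtract the electrode mean (default TRUE).
#' @param tol Relative truncation tolerance.
#' @return Named numeric vector of potentials (microvolts).
#' @export
dipole_potential <- function(model, montage, location, moment,
                             n_terms = model$max_terms,
                             average_reference = TRUE, tol = 1e-8) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  b <- sqrt(sum(location^2))
  r1 <- model$radii[1]
  if (b >= r1)
    stop("dipole location lies outside the innermost shell (|r| = ",
         format(b), " mm >= ", r1, " mm)")
  if (all(moment == 0)) {
    v <- stats::setNames(numeric(length(montage$labels)), montage$labels)
    return(v)
  }
  zhat <- if (b > 1e-9) location / b else c(0, 0, 1)
  geo <- elec_geometry(montage$positions, zhat)
  ser <- forward_series(model, geo, b / r1, n_terms, tol)
  m_r <- sum(moment * zhat)
  m_tan <- drop(geo$that %*% moment)
  # 1e3: nA*m, mm, S/m -> microvolts
  scale <- 1e3 / (4 * pi * model$conductivities[1] * r1^2)
  v <- scale * (m_r * ser$Srad + m_tan * ser$Stan)
  if (average_reference) v <- v - mean(v)
  stats::setNames(v, montage$labels)
}

#' Closed-form dipole potential in a homogeneous sphere
#'
#' Exact surface potential of a dipole inside a homogeneous conducting sphere
#' with an insulating exterior, from the closed-form summation of the
#' image-series (no truncation).  Serves as the independent oracle for the
#' multishell series in the equal-conductivity limit.
#'
#' @inheritParams dipole_potential
#' @param radius Sphere radius (mm).
#' @param conductivity Conductivity (S/m).
#' @export
dipole_potential_homogeneous <- function(montage, location, moment,
                                         radius, conductivity,
                                         average_reference = TRUE) {
  b <- sqrt(sum(location^2))
  if (b >= radius) stop("dipole outside the sphere")
  zhat <- if (b > 1e-9) location / b else c(0, 0, 1)
  geo <- elec_geometry(montage$positions, zhat)
  x <- geo$cosa; s <- geo$sina
  f <- b / radius
  FF <- sqrt(pmax(1 - 2 * f * x + f^2, 1e-300))
  if (f > 1e-9) {
    Srad <- 2 * (x - f) / FF^3 + (1 / FF - 1) / f
  } else {
    Srad <- 3 * x
  }
  Stan <- 2 * s / FF^3 + s * (FF + 1) / (FF * (1 - f * x + FF))
  m_r <- sum(moment * zhat)
  m_tan <- drop(geo$that %*% moment)
  scale <- 1e3 / (4 * pi * conductivity * radius^2)
  v <- scale * (m_r * Srad + m_tan * Stan)
  if (average_reference) v <- v - mean(v)
  stats::setNames(v, montage$labels)
}

#' Lead field for a source grid
#'
#' Gain tensor gain[e, g, o]: average-referenced scalp potential (microvolts)
#' at electrode e for a unit dipole (1 nA m) at grid point g oriented along
#' axis o.
#'
#' @param model A \code{sphere_model}.
#' @param montage An \code{electrode_montage}.
#' @param grid A \code{source_grid}.
#' @param n_terms,tol Series truncation controls.
#' @return Object of class \code{lead_field}: list with \code{gain}
#'   (E x P x 3 array), \code{montage}, \code{grid}.
#' @export
compute_leadfield <- function(model, montage, grid,
                              n_terms = model$max_terms, tol = 1e-8) {
  pts <- grid$points
  E <- length(montage$labels); P <- nrow(pts)
  gain <- array(0, c(E, P, 3))
  r1 <- model$radii[1]
  scale <- 1e3 / (4 * pi * model$conductivities[1] * r1^2)
  for (g in seq_len(P)) {
    loc <- pts[g, ]
    b <- sqrt(sum(loc^2))
    zhat <- if (b > 1e-9) loc / b else c(0, 0, 1)
    geo <- elec_geometry(montage$positions, zhat)
    ser <- forward_series(model, geo, b / r1, n_terms, tol)
    for (o in 1:3) {
      v <- scale * (zhat[o] * ser$Srad + geo$that[, o] * ser$Stan)
      gain[, g, o] <- v - mean(v)
    }
  }
  dimnames(gain) <- list(montage$labels, NULL, c("x", "y", "z"))
  structure(list(gain = gain, montage = montage, grid = grid,
                 model = list(radii = model$radii,
                              conductivities = model$conductivities)),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  d <- dim(x$gain)
  cat("Lead field:", d[1], "electrodes x", d[2], "grid points x 3 orientations\n")
  invisible(x)
}

#' Average-reference a multichannel signal
#'
#' Subtracts the instantaneous channel mean from every sample.
#'
#' @param signals channels x time matrix.
#' @return Matrix of the same shape with zero channel mean at every sample.
#' @export
apply_average_reference <- function(signals) {
  signals <- as.matrix(signals)
  if (nrow(signals) < 2) stop("average reference requires at least 2 channels")
  sweep(signals, 2, colMeans(signals), "-")
}
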