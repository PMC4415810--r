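#' Standard 10-20 electrode montage on a sphere
#'
#' Builds the canonical 10-20 scalp montage by the textbook arc construction
#' on a sphere: nasion, inion and the two preauricular points lie on the
#' equator, Cz at the vertex, the midline and central chains at 20% arc steps
#' (36 degrees), and the circumferential ring (Fp1/Fp2, F7/F8, T3/T4, T5/T6,
#' O1/O2) at 10% above the equator (72 degrees inclination).  F3/F4 and P3/P4
#' are great-circle midpoints of Fz--F7/F8 and Pz--T5/T6.
#'
#' Coordinates: origin at the sphere centre, +x right, +y anterior,
#' +z superior, millimetres.
#'
#' @param n_channels 19 (classic) or 21 (adds Fpz and Oz).
#' @param scalp_radius Radius of the scalp sphere in mm on which the
#'   electrodes sit.
#' @return An object of class \code{electrode_montage}: list with
#'   \code{labels} and \code{positions} (n x 3 matrix, mm).
#' @examples
#' m <- standard_montage_1020(19)
#' m$positions["Cz", ]  # the vertex
#' @export
standard_montage_1020 <- function(n_channels = 19, scalp_radius = 70) {
  if (!n_channels %in% c(19L, 21L))
    stop("unsupported channel count: ", n_channels, " (must be 19 or 21)")
  sph <- function(incl_deg, az_deg) {
    th <- incl_deg * pi / 180; ph <- az_deg * pi / 180
    c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
  }
  gc_mid <- function(p, q) { v <- p + q; v / sqrt(sum(v^2)) }
  ring <- 72
  pos <- list(
    Fp1 = sph(ring, -18), Fp2 = sph(ring, 18),
    F7 = sph(ring, -54), F8 = sph(ring, 54),
    T3 = sph(ring, -90), T4 = sph(ring, 90),
    T5 = sph(ring, -126), T6 = sph(ring, 126),
    O1 = sph(ring, -162), O2 = sph(ring, 162),
    Fpz = sph(ring, 0), Oz = sph(ring, 180),
    Fz = sph(36, 0), Cz = c(0, 0, 1), Pz = sph(36, 180),
    C3 = sph(36, -90), C4 = sph(36, 90)
  )
  pos$F3 <- gc_mid(pos$Fz, pos$F7); pos$F4 <- gc_mid(pos$Fz, pos$F8)
  pos$P3 <- gc_mid(pos$Pz, pos$T5); pos$P4 <- gc_mid(pos$Pz, pos$T6)
  labels <- if (n_channels == 19L) {
    c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
      "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  } else {
    c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
      "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "Oz", "O2")
  }
  P <- do.call(rbind, pos[labels]) * scalp_radius
  rownames(P) <- labels
  colnames(P) <- c("x", "y", "z")
  structure(list(labels = labels, positions = P, scalp_radius = scalp_radius),
            class = "electrode_montage")
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat("10-20 electrode montage:", length(x$labels), "channels on a",
      x$scalp_radius, "mm sphere\n")
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Export a montage as TSV
#'
#' Writes columns label, x, y, z (mm).
#' @param montage An \code{electrode_montage}.
#' @param path Output file path.
#' @export
write_montage_tsv <- function(montage, path) {
  df <- data.frame(label = montage$labels,
                   montage$positions,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
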