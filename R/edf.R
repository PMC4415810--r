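# Minimal EDF (European Data Format) reader/writer.  EDF is an ASCII header
# (256 bytes + 256 per signal) followed by 16-bit little-endian integer data
# records; all channels here share one sampling rate and 1-second records.
# No R EDF package is available in this environment, so the format is
# implemented directly against the published specification.

edf_pad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording as EDF with a TSV annotation sidecar
#'
#' 16-bit EDF; each channel is scaled to its own symmetric physical range.
#' Annotations (if present) go to a sidecar TSV with the same base name.
#'
#' @param recording An \code{eeg_recording}.
#' @param path Output path ending in .edf.
#' @return Invisibly, the paths written.
#' @export
write_recording <- function(recording, path) {
  x <- recording$data
  fs <- recording$fs
  if (is.null(x) || length(x) == 0) stop("empty recording")
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  C <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- x[, 1:(n_rec * fs), drop = FALSE]
  pmaxs <- pmax(apply(abs(x), 1, max), 1e-6)
  pmaxs <- ceiling(pmaxs * 10) / 10
  if (any(pmaxs >= 1e7)) stop("amplitudes exceed representable physical range")
  labels <- recording$channels %||% rownames(x) %||% paste0("ch", seq_len(C))
  con <- file(path, "wb")
  on.exit(close(con))
  wa <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wa(edf_pad("0", 8))
  wa(edf_pad("synthetic subject", 80))
  wa(edf_pad("burstnet recording", 80))
  wa(edf_pad("01.01.00", 8)); wa(edf_pad("00.00.00", 8))
  wa(edf_pad(256 * (1 + C), 8))
  wa(edf_pad("", 44))
  wa(edf_pad(n_rec, 8))
  wa(edf_pad("1", 8))
  wa(edf_pad(C, 4))
  for (l in labels) wa(edf_pad(l, 16))
  for (i in seq_len(C)) wa(edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(C)) wa(edf_pad("uV", 8))
  for (i in seq_len(C)) wa(edf_pad(format(-pmaxs[i], nsmall = 1), 8))
  for (i in seq_len(C)) wa(edf_pad(format(pmaxs[i], nsmall = 1), 8))
  for (i in seq_len(C)) wa(edf_pad("-32768", 8))
  for (i in seq_len(C)) wa(edf_pad("32767", 8))
  for (i in seq_len(C)) wa(edf_pad("none", 80))
  for (i in seq_len(C)) wa(edf_pad(fs, 8))
  for (i in seq_len(C)) wa(edf_pad("", 32))
  scale <- 65535 / (2 * pmaxs)
  for (r in seq_len(n_rec)) {
    seg <- x[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    dig <- round(seg * scale - 0.5)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  tsv <- sub("\\.edf$", ".tsv", path)
  if (!is.null(recording$annotations) && nrow(recording$annotations) > 0)
    write_annotations_tsv(recording$annotations, tsv)
  invisible(c(edf = path, annotations = tsv))
}

#' Read an EDF recording and its annotation sidecar
#'
#' @param path EDF file path.
#' @param annotations_path TSV sidecar (onset, duration, label); defaults to
#'   the EDF path with a .tsv extension.  Missing sidecar gives an empty
#'   annotation set with a warning.
#' @return An \code{eeg_recording} (data in microvolts).
#' @export
read_recording <- function(path, annotations_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (nchar(s, type = "bytes") < n) stop("corrupt EDF header: truncated file")
    trimws(s)
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  if (is.na(hdr_bytes)) stop("corrupt EDF header: field 'header bytes' not numeric")
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  if (is.na(n_rec)) stop("corrupt EDF header: field 'number of records' not numeric")
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  if (is.na(rec_dur) || rec_dur <= 0)
    stop("corrupt EDF header: field 'record duration' invalid")
  C <- suppressWarnings(as.integer(rd(4)))
  if (is.na(C) || C < 1) stop("corrupt EDF header: field 'number of signals' invalid")
  labels <- vapply(seq_len(C), function(i) rd(16), "")
  for (i in seq_len(C)) rd(80)
  dims <- vapply(seq_len(C), function(i) rd(8), "")
  if (!all(toupper(dims) %in% c("UV", "")))
    stop("unit mismatch: expected uV channels, got ", paste(unique(dims), collapse = ", "))
  pmin_v <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  pmax_v <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  dmin_v <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  dmax_v <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  for (i in seq_len(C)) rd(80)
  spr <- as.integer(vapply(seq_len(C), function(i) rd(8), ""))
  for (i in seq_len(C)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed sampling rates are not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, C, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = C * spr[1], size = 2, endian = "little")
    m <- matrix(raw, nrow = spr[1])           # samples x channels
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(m)
  }
  for (i in seq_len(C)) {
    g <- (pmax_v[i] - pmin_v[i]) / (dmax_v[i] - dmin_v[i])
    data[i, ] <- (data[i, ] - dmin_v[i]) * g + pmin_v[i]
  }
  rownames(data) <- labels
  ann_path <- annotations_path %||% sub("\\.edf$", ".tsv", path)
  ann <- if (file.exists(ann_path)) {
    read_annotations_tsv(ann_path)
  } else {
    warning("no annotation sidecar found at ", ann_path)
    data.frame(onset = numeric(0), duration = numeric(0),
               label = character(0), stringsAsFactors = FALSE)
  }
  structure(list(data = data, fs = fs, channels = labels, annotations = ann),
            class = "eeg_recording")
}
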