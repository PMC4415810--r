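# Burst/suppression phase labeling and phase-wise concatenation.

#' Label burst and suppression phases by amplitude
#'
#' Sliding-window peak-to-peak classification standing in for visual review:
#' consecutive windows of \code{window} seconds are labeled burst if any
#' channel's peak-to-peak amplitude reaches \code{burst_threshold}, and
#' suppression if every channel stays below \code{suppression_threshold};
#' windows in between remain unlabeled.  Adjacent windows with the same label
#' are merged into annotations.
#'
#' @param recording An \code{eeg_recording} (list with \code{data} channels x
#'   samples in microvolts and \code{fs}).
#' @param burst_threshold Peak-to-peak threshold for bursts (microvolts).
#'   Window-level thresholds sit well below the whole-burst clinical
#'   amplitude band because a sub-second window on a single channel sees
#'   only part of a slow-wave cycle.
#' @param suppression_threshold Upper peak-to-peak bound for suppression.
#' @param window Window length in seconds.
#' @return Data frame with columns onset (s), duration (s), label.
#' @export
label_phases_by_amplitude <- function(recording, burst_threshold = 30,
                                      suppression_threshold = 15,
                                      window = 0.5) {
  if (burst_threshold <= 0 || suppression_threshold <= 0 ||
      burst_threshold <= suppression_threshold)
    stop("thresholds must be positive with burst_threshold > suppression_threshold")
  x <- recording$data; fs <- recording$fs
  wn <- round(window * fs)
  if (wn > ncol(x)) stop("window longer than the recording")
  nw <- ncol(x) %/% wn
  labels <- character(nw)
  for (w in seq_len(nw)) {
    sl <- x[, ((w - 1) * wn + 1):(w * wn), drop = FALSE]
    pp <- apply(sl, 1, function(r) diff(range(r)))
    labels[w] <- if (max(pp) >= burst_threshold) "burst"
    else if (max(pp) < suppression_threshold) "suppression"
    else "unlabeled"
  }
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values != "unlabeled"
  data.frame(onset = starts[keep] * wn / fs,
             duration = runs$lengths[keep] * wn / fs,
             label = runs$values[keep],
             stringsAsFactors = FALSE)
}

#' Concatenate phase segments to a fixed duration
#'
#' Cuts the annotated intervals of one phase out of the recording (earliest
#' first), truncating the last so the concatenated duration is exactly
#' \code{target_duration} seconds.  Interval boundaries use half-open
#' 0-based sample conventions; the concatenation joins are recorded so
#' spectral epochs can avoid straddling them.  Annotated intervals shorter
#' than one second are skipped.
#'
#' @param recording An \code{eeg_recording}.
#' @param annotations Data frame (onset, duration, label); defaults to the
#'   recording's own annotations.
#' @param phase "burst" or "suppression".
#' @param target_duration Seconds of phase data required.
#' @param min_segment Minimum usable annotated segment length (s).
#' @return Object of class \code{phase_segments}: \code{data} (channels x
#'   samples), \code{fs}, \code{phase}, \code{intervals} (source sample
#'   intervals), \code{joins} (sample offsets of concatenation joins).
#' @export
concatenate_phase_segments <- function(recording, annotations = NULL,
                                       phase = c("burst", "suppression"),
                                       target_duration = 60,
                                       min_segment = 1) {
  phase <- match.arg(phase)
  ann <- annotations %||% recording$annotations
  if (is.null(ann) || nrow(ann) == 0) stop("no annotations available")
  fs <- recording$fs
  sel <- ann[ann$label == phase & ann$duration >= min_segment, , drop = FALSE]
  sel <- sel[order(sel$onset), , drop = FALSE]
  avail <- sum(sel$duration)
  if (avail < target_duration)
    stop(sprintf("only %.2f s of %s phase annotated; %.2f s requested (deficit %.2f s)",
                 avail, phase, target_duration, target_duration - avail))
  need <- round(target_duration * fs)
  pieces <- list(); intervals <- list(); joins <- integer(0)
  got <- 0L
  for (i in seq_len(nrow(sel))) {
    s0 <- round(sel$onset[i] * fs)
    s1 <- round((sel$onset[i] + sel$duration[i]) * fs)
    s1 <- min(s1, ncol(recording$data))
    take <- min(s1 - s0, need - got)
    if (take <= 0) break
    pieces[[length(pieces) + 1L]] <- recording$data[, (s0 + 1):(s0 + take), drop = FALSE]
    intervals[[length(intervals) + 1L]] <- c(s0, s0 + take)
    got <- got + take
    if (got >= need) break
    joins <- c(joins, got)
  }
  structure(list(data = do.call(cbind, pieces), fs = fs, phase = phase,
                 intervals = intervals, joins = joins),
            class = "phase_segments")
}

#' @export
print.phase_segments <- function(x, ...) {
  cat(sprintf("%s segments: %d channels x %d samples (%.1f s at %g Hz), %d joins\n",
              x$phase, nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs,
              length(x$joins)))
  invisible(x)
}

#' Write annotations as a TSV sidecar
#' @param annotations Data frame (onset, duration, label).
#' @param path Output path.
#' @export
write_annotations_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV annotation sidecar
#' @param path File with columns onset, duration, label.
#' @export
read_annotations_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
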