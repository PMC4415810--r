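# End-to-end orchestration: configuration, per-subject analysis
# (phases -> spectra -> DICS -> RPDC -> statistics) and cohort aggregation.

#' Analysis configuration
#'
#' All tunable parameters of the pipeline with their defaults.  The
#' \code{"desk"} preset reduces the Monte-Carlo counts (surrogates 50,
#' bootstrap 100) for interactive desk-scale runs; \code{"full"} uses the
#' publication-scale counts.
#'
#' @param preset "desk" or "full".
#' @param ... Named overrides of any configuration field.
#' @return Object of class \code{bs_config}.
#' @export
bs_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    radii = c(58, 60, 62, 65, 70),
    conductivities = c(0.33, 0.33, 1.79, 0.04, 0.33),
    n_channels = 19,
    grid_spacing = 10,
    band = c(1, 4),
    epoch = 1,
    time_bandwidth = 2,
    k_tapers = 3,
    lambda = 0.05,
    lambda_ref = 0.5,
    exclusion_mm = 20,
    max_sources = 8,
    target_duration = 60,
    burst_threshold = 30,
    suppression_threshold = 15,
    label_window = 0.5,
    n_perm = if (preset == "desk") 50 else 100,
    n_boot = if (preset == "desk") 100 else 1000,
    alpha = 0.01,
    decimate_fs = 32,
    max_order = 10,
    seed = 1,
    preset = preset
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown configuration field: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "bs_config")
}

#' @export
print.bs_config <- function(x, ...) {
  cat("burstnet configuration (preset:", x$preset, ")\n")
  cat(sprintf("  grid %g mm, band %g-%g Hz, lambda %g (ref %g), %d surrogates, %d bootstraps\n",
              x$grid_spacing, x$band[1], x$band[2], x$lambda, x$lambda_ref,
              x$n_perm, x$n_boot))
  invisible(x)
}

# Build (or reuse) the forward machinery for a config.
pipeline_forward <- function(config, montage = NULL) {
  model <- build_sphere_model(config$radii, config$conductivities)
  montage <- montage %||% standard_montage_1020(config$n_channels)
  grid <- build_source_grid(model, config$grid_spacing)
  lf <- compute_leadfield(model, montage, grid)
  list(model = model, montage = montage, grid = grid, leadfield = lf)
}

# Analyze one phase of one recording; fwd from pipeline_forward().
analyze_phase <- function(recording, annotations, phase, config, fwd, seed) {
  seg <- concatenate_phase_segments(recording, annotations, phase,
                                    target_duration = config$target_duration)
  sur <- surrogate_source_threshold(
    seg, fwd$leadfield, lambda = config$lambda, lambda_ref = config$lambda_ref,
    n_perm = config$n_perm, band = config$band,
    exclusion_mm = config$exclusion_mm, seed = derive_seed(seed, 41),
    epoch = config$epoch, time_bandwidth = config$time_bandwidth,
    k = config$k_tapers)
  srcs <- iterate_coherent_sources(sur$power_map, sur,
                                   exclusion_mm = config$exclusion_mm,
                                   max_sources = config$max_sources)
  sig <- extract_source_signals(seg$data, srcs, fwd$leadfield, config$lambda)
  dec <- decimate_signals(sig, seg$fs, config$decimate_fs)
  dsig <- bandpass_filtfilt(dec$signals, dec$fs, config$band)
  rp <- if (nrow(dsig) >= 2) {
    rpdc_edges(dsig, dec$fs, freqs = config$band[1]:config$band[2],
               n_boot = config$n_boot, alpha = config$alpha,
               max_order = config$max_order, seed = derive_seed(seed, 43))
  } else NULL
  cs_src <- multitaper_csd(dsig, fs = dec$fs, epoch = config$epoch,
                           time_bandwidth = config$time_bandwidth,
                           k = config$k_tapers)
  Cs <- band_csd(cs_src, config$band)
  p <- Re(diag(matrix(Cs, nrow(dsig), nrow(dsig))))
  # interaction strength: mean reference coherence over the strongest
  # activity peaks (defined for any number of accepted sources)
  cand <- setdiff(burstnet:::nai_local_maxima(sur$power_map), sur$reference)
  cand <- cand[order(sur$power_map$nai[cand], decreasing = TRUE)]
  cand <- utils::head(cand, 5)
  msc <- if (length(cand) > 0)
    mean(srcs$coherence_map$coherence[cand]) else 0
  pooled <- pooled_power_spectrum(multitaper_csd(
    seg, epoch = config$epoch, time_bandwidth = config$time_bandwidth,
    k = config$k_tapers))
  list(segments_duration = ncol(seg$data) / seg$fs,
       surrogate = sur,
       sources = srcs,
       source_signals = dsig,
       source_fs = dec$fs,
       rpdc = rp,
       pooled_spectrum = pooled,
       band_peak = find_band_peak(pooled, config$band),
       mean_source_power = mean(p),
       mean_source_coherence = msc)
}

#' Run the full analysis for one subject
#'
#' Labels phases by amplitude (unless told to trust existing annotations),
#' concatenates 60 s of each phase, and runs the multitaper / DICS / RPDC /
#' surrogate chain on both.
#'
#' @param recording An \code{eeg_recording}.
#' @param config A \code{bs_config}.
#' @param fwd Optional precomputed forward structure from an earlier run
#'   (shared across subjects for speed).
#' @param use_annotations Use the recording's annotations instead of
#'   amplitude-based relabeling.
#' @param subject Identifier stored with the result.
#' @return Object of class \code{bs_subject}: per-phase results
#'   (\code{phases$burst}, \code{phases$suppression}), \code{snr_db},
#'   \code{annotations}, \code{config}.
#' @export
run_subject <- function(recording, config = bs_config(), fwd = NULL,
                        use_annotations = FALSE, subject = 1L) {
  fwd <- fwd %||% pipeline_forward(config)
  ann <- if (use_annotations) recording$annotations
  else label_phases_by_amplitude(recording, config$burst_threshold,
                                 config$suppression_threshold,
                                 config$label_window)
  seed <- derive_seed(config$seed, 3, subject)
  phases <- list()
  for (ph in c("burst", "suppression")) {
    phases[[ph]] <- tryCatch(
      analyze_phase(recording, ann, ph, config, fwd, derive_seed(seed, 5)),
      error = function(e) stop("stage '", ph, "' failed for subject ",
                               subject, ": ", conditionMessage(e)))
  }
  segB <- concatenate_phase_segments(recording, ann, "burst",
                                     config$target_duration)
  segS <- concatenate_phase_segments(recording, ann, "suppression",
                                     config$target_duration)
  snr <- relative_snr_db(segB, segS, config$band)
  structure(list(subject = subject, phases = phases, snr_db = snr,
                 annotations = ann, config = config),
            class = "bs_subject")
}

#' @export
print.bs_subject <- function(x, ...) {
  cat("burstnet subject", x$subject, "\n")
  cat(sprintf("  relative burst/suppression SNR: %.2f dB\n", x$snr_db))
  for (ph in names(x$phases)) {
    p <- x$phases[[ph]]
    cat(sprintf("  %s: %d sources (threshold %.3f), band peak %g-%g Hz\n",
                ph, nrow(p$sources$sources), p$surrogate$threshold,
                p$band_peak[1], p$band_peak[2]))
    if (!is.null(p$rpdc)) {
      acc <- p$rpdc$edges[p$rpdc$edges$accepted, , drop = FALSE]
      cat(sprintf("    accepted directed edges: %d\n", nrow(acc)))
    }
  }
  invisible(x)
}

#' @export
summary.bs_subject <- function(object, ...) {
  for (ph in names(object$phases)) {
    cat("==", ph, "phase\n")
    print(object$phases[[ph]]$sources)
    if (!is.null(object$phases[[ph]]$rpdc)) {
      e <- object$phases[[ph]]$rpdc$edges
      print(e[e$accepted, c("from", "to", "lambda", "trt"), drop = FALSE],
            row.names = FALSE)
    }
  }
  invisible(object)
}

#' Run a cohort analysis
#'
#' Either analyzes a list of recordings or simulates \code{n_subjects} from
#' the default generator, then aggregates: grand-average coherence maps
#' (mean of per-subject maps normalized to their maxima) and the
#' burst-versus-suppression phase contrast.
#'
#' @param recordings List of \code{eeg_recording}s, or NULL to simulate.
#' @param n_subjects Number of subjects to simulate when \code{recordings}
#'   is NULL.
#' @param config A \code{bs_config}.
#' @param ... Passed to \code{\link{simulate_cohort}}.
#' @return Object of class \code{bs_cohort}: \code{subjects} (list of
#'   \code{bs_subject}), \code{contrast} (\code{phase_contrast} or NULL),
#'   \code{grand_maps} (per-phase grand-average coherence vectors),
#'   \code{ground_truths} when simulated.
#' @export
run_cohort <- function(recordings = NULL, n_subjects = 13,
                       config = bs_config(), ...) {
  fwd <- pipeline_forward(config)
  gts <- NULL
  if (is.null(recordings)) {
    sims <- simulate_cohort(n_subjects, model = fwd$model,
                            montage = fwd$montage, seed = config$seed, ...)
    recordings <- lapply(sims, `[[`, "recording")
    gts <- lapply(sims, `[[`, "ground_truth")
  }
  subjects <- vector("list", length(recordings))
  failed <- logical(length(recordings))
  for (i in seq_along(recordings)) {
    subjects[[i]] <- tryCatch(
      run_subject(recordings[[i]], config, fwd, subject = i),
      error = function(e) {
        message("subject ", i, " failed: ", conditionMessage(e))
        failed[i] <<- TRUE
        NULL
      })
  }
  ok <- subjects[!failed & !vapply(subjects, is.null, TRUE)]
  grand <- list()
  for (ph in c("burst", "suppression")) {
    maps <- lapply(ok, function(s) {
      cmv <- s$phases[[ph]]$sources$coherence_map$coherence
      cmv / max(cmv)
    })
    grand[[ph]] <- Reduce(`+`, maps) / length(maps)
  }
  contrast <- if (length(ok) >= 2) compare_phases(ok) else {
    warning("fewer than 2 complete subjects; phase contrast skipped")
    NULL
  }
  structure(list(subjects = ok, contrast = contrast, grand_maps = grand,
                 grid = fwd$grid, ground_truths = gts, config = config,
                 n_failed = sum(failed)),
            class = "bs_cohort")
}

#' @export
print.bs_cohort <- function(x, ...) {
  cat("burstnet cohort:", length(x$subjects), "subjects analyzed",
      if (x$n_failed > 0) paste0("(", x$n_failed, " failed)"), "\n")
  snrs <- vapply(x$subjects, `[[`, 1, "snr_db")
  cat(sprintf("  relative SNR range: %.2f-%.2f dB\n", min(snrs), max(snrs)))
  if (!is.null(x$contrast)) print(x$contrast)
  invisible(x)
}

#' Export a map as TSV (x, y, z, value)
#' @param values Per-grid-point values.
#' @param grid A \code{source_grid}.
#' @param path Output path.
#' @export
write_map_tsv <- function(values, grid, path) {
  df <- data.frame(grid$points, value = values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
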