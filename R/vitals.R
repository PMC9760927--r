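# Per-minute RR/HR extraction rules and the end-to-end pipeline.

#' Band configuration for the RR/HR extraction rules
#'
#' Frequency bands and thresholds of the spectral vital-sign rules. RR is
#' the global magnitude maximum above 0.5 Hz capped at 2.5 Hz (breathing is
#' the dominant phase excursion, so that maximum is the breathing
#' fundamental). HR is searched among the five largest local maxima from
#' 1.5 Hz upward -- or from RR + 0.25 Hz when RR reaches 1.5 Hz -- and the
#' lowest candidate with at least one harmonic is taken. The HR ceiling
#' defaults to 5.5 Hz (330 beats/min), the physiological ceiling for the
#' neonate-sized model the pad was validated on.
#'
#' @param rr_lo_hz,rr_hi_hz RR search band, Hz (lower edge exclusive).
#' @param hr_start_hz Default lower edge of the HR search, Hz.
#' @param hr_offset_hz Offset added to RR when RR >= `hr_start_hz`.
#' @param hr_hi_hz Upper edge of the HR search, Hz.
#' @param n_maxima Number of spectral maxima the HR rule inspects.
#' @param harmonic_tol_hz Frequency tolerance when matching a peak near
#'   twice a candidate frequency, Hz. The default 0.025 Hz is 1.5 bins of a
#'   60 s window; for coarser spectra the effective tolerance never drops
#'   below 1.5 bins. Keeping it near one bin matters: a wide tolerance lets
#'   the cardiac harmonic validate a nearby breathing harmonic instead of
#'   the cardiac fundamental.
#' @param harmonic_min_rel_amp Minimum harmonic magnitude relative to the
#'   candidate peak.
#' @param peak_min_rel_amp Minimum HR-candidate magnitude relative to the
#'   largest local maximum in the search band. On measured spectra the
#'   "five maxima" are prominent peaks; this floor keeps numerical-floor
#'   and noise ripples from posing as candidates.
#' @param noise_floor_factor RR validity: the band maximum must exceed this
#'   multiple of the median in-band magnitude.
#' @param artifact_threshold_k Motion-artifact flagging threshold: a second
#'   is flagged when its phase-increment RMS exceeds this multiple of the
#'   record's median per-second RMS.
#' @return An object of class `band_config`.
#' @export
band_config <- function(rr_lo_hz = 0.5, rr_hi_hz = 2.5,
                        hr_start_hz = 1.5, hr_offset_hz = 0.25,
                        hr_hi_hz = 5.5, n_maxima = 5L,
                        harmonic_tol_hz = 0.025,
                        harmonic_min_rel_amp = 0.05,
                        peak_min_rel_amp = 0.05,
                        noise_floor_factor = 3,
                        artifact_threshold_k = 8) {
  if (!(rr_lo_hz < rr_hi_hz))
    fv_stop("vitals", "invalid-params", "need rr_lo_hz < rr_hi_hz")
  if (hr_start_hz < rr_lo_hz)
    fv_stop("vitals", "invalid-params", "need hr_start_hz >= rr_lo_hz")
  if (n_maxima < 1L)
    fv_stop("vitals", "invalid-params", "need n_maxima >= 1")
  structure(list(rr_lo_hz = rr_lo_hz, rr_hi_hz = rr_hi_hz,
                 hr_start_hz = hr_start_hz, hr_offset_hz = hr_offset_hz,
                 hr_hi_hz = hr_hi_hz, n_maxima = as.integer(n_maxima),
                 harmonic_tol_hz = harmonic_tol_hz,
                 harmonic_min_rel_amp = harmonic_min_rel_amp,
                 peak_min_rel_amp = peak_min_rel_amp,
                 noise_floor_factor = noise_floor_factor,
                 artifact_threshold_k = artifact_threshold_k),
            class = "band_config")
}

invalid_estimate <- function(reason) {
  list(valid = FALSE, bpm = NA_real_, freq_hz = NA_real_, reason = reason)
}

#' Estimate respiratory rate from a frame spectrum
#'
#' RR is the frequency of the global magnitude maximum on
#' `(rr_lo_hz, rr_hi_hz]`, converted to breaths/min and rounded to the
#' nearest integer. The estimate is invalid when no bin lies in the band or
#' when the band maximum does not exceed `noise_floor_factor` times the
#' median in-band magnitude (a flat spectrum carries no breathing peak).
#'
#' @param spec A `spectrum_frame`.
#' @param cfg A [band_config()].
#' @return A list with `valid`, `bpm`, `freq_hz` and (when invalid) a
#'   `reason` code.
#' @export
estimate_rr <- function(spec, cfg = band_config()) {
  stopifnot(inherits(spec, "spectrum_frame"))
  band <- which(spec$freqs > cfg$rr_lo_hz & spec$freqs <= cfg$rr_hi_hz)
  if (length(band) == 0L) return(invalid_estimate("empty-band"))
  i <- band[which.max(spec$mags[band])]
  if (!(spec$mags[i] > cfg$noise_floor_factor * stats::median(spec$mags[band])))
    return(invalid_estimate("below-noise-floor"))
  f <- spec$freqs[i]
  list(valid = TRUE, bpm = round(f * 60), freq_hz = f, reason = NA_character_)
}

#' Does a spectral peak have a harmonic?
#'
#' TRUE iff some local maximum of the spectrum lies within the harmonic
#' tolerance of `2 * f0` and its magnitude is at least
#' `harmonic_min_rel_amp` times the magnitude at `f0`. Returns FALSE when
#' `2 * f0` exceeds the Nyquist frequency. The effective tolerance is
#' `max(harmonic_tol_hz, 1.5 * resolution)` so that 30 s frames keep at
#' least 1.5 bins of slack.
#'
#' @param spec A `spectrum_frame`.
#' @param f0 Candidate fundamental frequency, Hz (on the grid).
#' @param cfg A [band_config()].
#' @return Logical scalar.
#' @export
has_harmonic <- function(spec, f0, cfg = band_config()) {
  stopifnot(inherits(spec, "spectrum_frame"))
  tol <- max(cfg$harmonic_tol_hz, 1.5 * spec$resolution_hz)
  target <- 2 * f0
  nyq <- spec$freqs[length(spec$freqs)]
  if (target > nyq + tol) return(FALSE)
  mag0 <- spec$mags[which.min(abs(spec$freqs - f0))]
  peaks <- find_local_maxima(spec, 0, nyq, k = Inf)
  any(abs(peaks$freq_hz - target) <= tol &
        peaks$mag >= cfg$harmonic_min_rel_amp * mag0)
}

#' Estimate heart rate from a frame spectrum
#'
#' The search starts at `hr_start_hz`, or at `rr_freq_hz + hr_offset_hz`
#' when the breathing frequency reaches `hr_start_hz` (so the breathing
#' fundamental can never be mistaken for the heartbeat). Among the
#' `n_maxima` largest local maxima in `(start, hr_hi_hz]`, the lowest
#' frequency that has at least one harmonic component is taken as the HR;
#' if none qualifies the estimate is invalid.
#'
#' @param spec A `spectrum_frame`.
#' @param rr_freq_hz Breathing frequency from [estimate_rr()], or `NA` if
#'   unavailable (the search then starts at `hr_start_hz`).
#' @param cfg A [band_config()].
#' @return A list with `valid`, `bpm`, `freq_hz` and (when invalid) a
#'   `reason` code.
#' @export
estimate_hr <- function(spec, rr_freq_hz = NA_real_, cfg = band_config()) {
  stopifnot(inherits(spec, "spectrum_frame"))
  f_start <- if (is.na(rr_freq_hz) || rr_freq_hz < cfg$hr_start_hz)
    cfg$hr_start_hz else rr_freq_hz + cfg$hr_offset_hz
  peaks <- find_local_maxima(spec, f_start, cfg$hr_hi_hz, k = Inf)
  if (nrow(peaks) == 0L) return(invalid_estimate("no-peaks"))
  peaks <- peaks[peaks$mag >= cfg$peak_min_rel_amp * peaks$mag[1L], ,
                 drop = FALSE]
  peaks <- utils::head(peaks, cfg$n_maxima)
  ok <- vapply(peaks$freq_hz, function(f) has_harmonic(spec, f, cfg), logical(1))
  if (!any(ok)) return(invalid_estimate("no-harmonic-peak"))
  f <- min(peaks$freq_hz[ok])
  list(valid = TRUE, bpm = round(f * 60), freq_hz = f, reason = NA_character_)
}

#' Per-second motion-artifact flags
#'
#' A second is flagged when the RMS of the first difference of the phase
#' over that second exceeds `threshold_k` times the record's median
#' per-second RMS. Motion transients raise the local phase slope far above
#' the physiological baseline, so the ratio separates them cleanly.
#'
#' @param phase An unwrapped [phase_series()].
#' @param threshold_k Multiplier on the record-median per-second RMS;
#'   `Inf` disables flagging.
#' @return Logical vector, one flag per whole second of the record.
#' @export
artifact_seconds <- function(phase, threshold_k = 8) {
  stopifnot(inherits(phase, "phase_series"))
  fs <- phase$fs
  n_sec <- floor(duration_of(phase))
  d <- c(0, diff(phase$values))
  rms <- vapply(seq_len(n_sec), function(s) {
    idx <- ((s - 1L) * round(fs) + 1L):(s * round(fs))
    sqrt(mean(d[idx]^2))
  }, numeric(1))
  thr <- threshold_k * stats::median(rms)
  if (!is.finite(thr)) return(rep(FALSE, n_sec))
  rms > thr
}

#' Is a given minute distorted by motion artifact?
#'
#' @param phase An unwrapped [phase_series()].
#' @param minute_index 1-based minute number, within the record.
#' @param threshold_k See [artifact_seconds()].
#' @return Logical scalar: TRUE iff any second of that minute is flagged.
#' @export
detect_distortion <- function(phase, minute_index, threshold_k = 8) {
  n_min <- floor(duration_of(phase) / 60)
  if (minute_index < 1L || minute_index > n_min)
    fv_stop("vitals", "range-error",
            sprintf("minute %d outside record (1..%d)", minute_index, n_min))
  flags <- artifact_seconds(phase, threshold_k)
  any(flags[((minute_index - 1L) * 60L + 1L):(minute_index * 60L)])
}

#' Run the full vital-sign pipeline on a coupler record
#'
#' Equalize, demodulate, unwrap, flag artifact seconds, frame per minute
#' (60 s windows; the longest clean 30 s for distorted minutes), compute
#' Hamming spectra, and apply the RR and HR rules. Minutes with no clean
#' 30 s stretch are emitted with both vitals invalid. A valid minute with
#' RR >= HR is physiologically implausible and is reported via a message,
#' never swapped or altered.
#'
#' @param record A [coupler_record()] of at least 60 s.
#' @param cfg A [band_config()].
#' @param equalize_method Passed to [equalize()] as `method`.
#' @return A `vitals_table`: a data frame with one row per minute and
#'   columns `minute`, `rr_bpm`, `hr_bpm`, `rr_freq_hz`, `hr_freq_hz`,
#'   `valid_rr`, `valid_hr`, `distorted`, plus attributes `band_config`,
#'   `equalization` and `phase` (the recovered phase series).
#' @examples
#' ph <- make_phase_signal(physio_params(rr_bpm = 77, hr_bpm = 158,
#'                                       noise_sd_rad = 0),
#'                         sampling_spec(250, 180))
#' vt <- run_pipeline(make_coupler_record(ph))
#' vt
#' @export
run_pipeline <- function(record, cfg = band_config(),
                         equalize_method = "minmax") {
  stopifnot(inherits(record, "coupler_record"), inherits(cfg, "band_config"))
  if (duration_of(record) < 60)
    fv_stop("vitals", "insufficient-length",
            sprintf("record is %.3g s; at least 60 s required",
                    duration_of(record)))
  eq <- equalize(record, method = equalize_method)
  phase <- unwrap_phase(demodulate(eq$record))
  art <- artifact_seconds(phase, cfg$artifact_threshold_k)
  frames <- frame_signal(phase, art)
  rows <- lapply(seq_along(frames), function(m) {
    fr <- frames[[m]]
    if (length(fr$samples) == 0L) {
      return(data.frame(minute = m, rr_bpm = NA_real_, hr_bpm = NA_real_,
                        rr_freq_hz = NA_real_, hr_freq_hz = NA_real_,
                        valid_rr = FALSE, valid_hr = FALSE, distorted = TRUE))
    }
    spec <- compute_spectrum(fr)
    rr <- estimate_rr(spec, cfg)
    hr <- estimate_hr(spec, rr$freq_hz, cfg)
    if (rr$valid && hr$valid && rr$bpm >= hr$bpm)
      message(sprintf(
        "[vitals] minute %d: RR (%g) >= HR (%g); physiologically RR < HR",
        m, rr$bpm, hr$bpm))
    data.frame(minute = m, rr_bpm = rr$bpm, hr_bpm = hr$bpm,
               rr_freq_hz = rr$freq_hz, hr_freq_hz = hr$freq_hz,
               valid_rr = rr$valid, valid_hr = hr$valid,
               distorted = fr$distorted)
  })
  out <- do.call(rbind, rows)
  attr(out, "band_config") <- cfg
  attr(out, "equalization") <- eq$report
  attr(out, "phase") <- phase
  class(out) <- c("vitals_table", "data.frame")
  out
}

#' @export
print.vitals_table <- function(x, ...) {
  cat(sprintf("Per-minute vital signs (%d minute%s)\n", nrow(x),
              if (nrow(x) == 1L) "" else "s"))
  print.data.frame(x, row.names = FALSE, digits = 5)
  cat(sprintf("valid RR: %d/%d, valid HR: %d/%d, distorted minutes: %d\n",
              sum(x$valid_rr), nrow(x), sum(x$valid_hr), nrow(x),
              sum(x$distorted)))
  invisible(x)
}

#' @export
summary.vitals_table <- function(object, ...) {
  rr <- object$rr_bpm[object$valid_rr]
  hr <- object$hr_bpm[object$valid_hr]
  out <- list(
    minutes = nrow(object),
    valid_rr = sum(object$valid_rr), valid_hr = sum(object$valid_hr),
    distorted = sum(object$distorted),
    rr_median = if (length(rr)) stats::median(rr) else NA_real_,
    hr_median = if (length(hr)) stats::median(hr) else NA_real_
  )
  class(out) <- "summary.vitals_table"
  out
}

#' @export
print.summary.vitals_table <- function(x, ...) {
  cat(sprintf("%d minute(s): %d valid RR (median %g breaths/min), %d valid HR (median %g beats/min), %d distorted\n",
              x$minutes, x$valid_rr, x$rr_median, x$valid_hr, x$hr_median,
              x$distorted))
  invisible(x)
}

#' @export
plot.vitals_table <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$minute, x$rr_bpm, type = "b", pch = 19,
                 xlab = "Minute", ylab = "RR (breaths/min)",
                 main = "Respiratory rate", ...)
  graphics::plot(x$minute, x$hr_bpm, type = "b", pch = 19,
                 xlab = "Minute", ylab = "HR (beats/min)",
                 main = "Heart rate", ...)
  invisible(x)
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("Phase series: %d samples at %g Hz (%.4g s), range [%.4g, %.4g] rad\n",
              length(x$values), x$fs, duration_of(x),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.phase_series <- function(x, ...) {
  graphics::plot(time_axis(x), x$values, type = "l",
                 xlab = "Time (s)", ylab = "Phase (rad)", ...)
  invisible(x)
}

#' @export
print.coupler_record <- function(x, ...) {
  cat(sprintf("Coupler record: 3 channels x %d samples at %g Hz (%.4g s)\n",
              nrow(x$u), x$fs, duration_of(x)))
  invisible(x)
}
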