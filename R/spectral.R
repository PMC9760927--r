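# Minute-wise framing and Hamming-windowed magnitude spectra with
# local-maxima detection.

#' Cut a phase record into per-minute analysis frames
#'
#' One non-overlapping frame per whole minute, aligned to minute
#' boundaries. A minute containing flagged artifact seconds contributes the
#' first 30 s of its longest clean run instead (marked `distorted`); a
#' minute with no clean 30 s run yields a zero-length distorted frame that
#' downstream stages mark invalid.
#'
#' @param phase A [phase_series()] of at least 60 s.
#' @param artifact_seconds Optional logical vector, one flag per whole
#'   second of the record (see [artifact_seconds()]); `TRUE` marks a second
#'   contaminated by motion artifact. `NULL` means the record is clean.
#' @return A list of `vitals_frame` objects with fields `samples`, `fs`,
#'   `start_s`, `length_s` (60 or 30) and `distorted`.
#' @export
frame_signal <- function(phase, artifact_seconds = NULL) {
  stopifnot(inherits(phase, "phase_series"))
  fs <- phase$fs
  n_min <- floor(duration_of(phase) / 60)
  if (n_min < 1L)
    fv_stop("spectral", "insufficient-length",
            sprintf("record is %.3g s; at least 60 s required",
                    duration_of(phase)))
  n_sec <- floor(duration_of(phase))
  if (is.null(artifact_seconds)) artifact_seconds <- rep(FALSE, n_sec)
  if (length(artifact_seconds) < n_min * 60L)
    fv_stop("spectral", "invalid-params",
            "artifact_seconds must cover every whole minute of the record")
  lapply(seq_len(n_min), function(m) {
    sec0 <- (m - 1L) * 60L
    flags <- artifact_seconds[sec0 + 1:60]
    mk <- function(start_s, length_s, distorted) {
      i0 <- round(start_s * fs)
      idx <- if (length_s > 0) (i0 + 1L):(i0 + round(length_s * fs)) else integer(0)
      structure(list(samples = phase$values[idx], fs = fs,
                     start_s = phase$t0 + start_s,
                     length_s = if (length_s > 0) length_s else 30,
                     distorted = distorted),
                class = "vitals_frame")
    }
    if (!any(flags)) return(mk(sec0, 60, FALSE))
    runs <- rle(!flags)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    clean <- which(runs$values)
    if (length(clean) == 0L || max(runs$lengths[clean]) < 30L)
      return(mk(sec0, 0, TRUE))
    best <- clean[which.max(runs$lengths[clean])]
    mk(sec0 + starts[best] - 1L, 30, TRUE)
  })
}

#' Hamming-windowed one-sided magnitude spectrum of a frame
#'
#' The frame is mean-removed (baseline drift otherwise dominates the
#' spectrum), multiplied by a periodic (DFT-even) Hamming window, and
#' transformed by a one-sided DFT. Magnitudes are scaled so a full-frame
#' cosine of amplitude `a` whose frequency falls on the grid reads `a` at
#' its bin; frequency resolution is `1/length_s` Hz. Zero-padding is off by
#' default -- at a 60 s window the grid spacing is exactly 1 breath/min --
#' with an optional integer padding factor for sub-bin interpolation.
#'
#' @param frame A `vitals_frame` from [frame_signal()], non-empty.
#' @param pad Integer zero-padding factor (1 = none).
#' @return A `spectrum_frame` with fields `freqs` (Hz, starting at 0),
#'   `mags` (>= 0), `resolution_hz` and `length_s`.
#' @export
compute_spectrum <- function(frame, pad = 1L) {
  stopifnot(inherits(frame, "vitals_frame"))
  n <- length(frame$samples)
  if (n == 0L)
    fv_stop("spectral", "empty-frame", "frame has no samples")
  x <- frame$samples - mean(frame$samples)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / n)
  nfft <- n * as.integer(pad)
  xw <- c(x * w, numeric(nfft - n))
  X <- stats::fft(xw)
  half <- floor(nfft / 2) + 1L
  mags <- Mod(X[seq_len(half)]) / sum(w)
  mags[-1L] <- 2 * mags[-1L]
  if (nfft %% 2L == 0L) mags[half] <- mags[half] / 2
  res <- frame$fs / nfft
  structure(list(freqs = (seq_len(half) - 1L) * res, mags = mags,
                 resolution_hz = 1 / frame$length_s, length_s = frame$length_s,
                 distorted = frame$distorted),
            class = "spectrum_frame")
}

#' Local spectral maxima in a band
#'
#' A local maximum is a bin strictly greater than both neighbours; a
#' plateau of equal bins flanked by lower values counts once, at its
#' leftmost bin. Peaks are restricted to `(f_lo, f_hi]`, sorted by
#' descending magnitude with frequency as tie-break (lower first), and
#' truncated to the `k` largest.
#'
#' @param spec A `spectrum_frame`.
#' @param f_lo,f_hi Band edges, Hz (`f_lo` exclusive, `f_hi` inclusive).
#' @param k Maximum number of peaks returned (`Inf` for all).
#' @return A data frame with columns `freq_hz`, `mag`, `rank` (1 = largest
#'   magnitude); zero rows if the band holds no local maximum.
#' @export
find_local_maxima <- function(spec, f_lo, f_hi, k = 5L) {
  stopifnot(inherits(spec, "spectrum_frame"))
  if (!(f_lo < f_hi))
    fv_stop("spectral", "invalid-params", "need f_lo < f_hi")
  m <- spec$mags
  runs <- rle(m)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  nr <- length(runs$values)
  is_max <- logical(nr)
  if (nr >= 3L)
    is_max[2:(nr - 1L)] <- runs$values[2:(nr - 1L)] > runs$values[1:(nr - 2L)] &
      runs$values[2:(nr - 1L)] > runs$values[3:nr]
  idx <- starts[is_max]
  f <- spec$freqs[idx]
  keep <- f > f_lo & f <= f_hi
  idx <- idx[keep]
  if (length(idx) == 0L)
    return(data.frame(freq_hz = numeric(0), mag = numeric(0),
                      rank = integer(0)))
  ord <- order(-m[idx], spec$freqs[idx])
  idx <- idx[ord]
  if (is.finite(k)) idx <- utils::head(idx, k)
  data.frame(freq_hz = spec$freqs[idx], mag = m[idx],
             rank = seq_along(idx))
}

#' @export
print.spectrum_frame <- function(x, ...) {
  cat(sprintf("Magnitude spectrum: %d bins, resolution %.4g Hz (%g s frame%s)\n",
              length(x$freqs), x$resolution_hz, x$length_s,
              if (isTRUE(x$distorted)) ", distorted" else ""))
  invisible(x)
}

#' @export
plot.spectrum_frame <- function(x, f_max = 8, ...) {
  sel <- x$freqs <= f_max
  graphics::plot(x$freqs[sel], x$mags[sel], type = "h",
                 xlab = "Frequency (Hz)", ylab = "Magnitude (rad)", ...)
  invisible(x)
}
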