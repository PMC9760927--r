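# Synthetic signal generation: physiologically structured interferometric
# phase signals and the corresponding 3x3-coupler photodetector outputs.

#' Sampling specification
#'
#' Describes the uniform time base of a simulated record. The pad hardware
#' digitizes far faster than any physiological component; 250 Hz is ample
#' for breathing and cardiac harmonics and keeps 3-minute records small.
#'
#' @param fs Sampling rate in Hz. Must be positive.
#' @param duration_s Record length in seconds. Must be positive.
#' @return An object of class `sampling_spec` with fields `fs`, `duration_s`
#'   and derived sample count `n = round(fs * duration_s)`.
#' @examples
#' sampling_spec(250, 180)
#' @export
sampling_spec <- function(fs = 250, duration_s = 180) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    fv_stop("synth", "invalid-params", "fs must be a positive number")
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s <= 0)
    fv_stop("synth", "invalid-params", "duration_s must be a positive number")
  structure(list(fs = fs, duration_s = duration_s,
                 n = as.integer(round(fs * duration_s))),
            class = "sampling_spec")
}

#' Physiological phase-signal parameters
#'
#' Parameters of the simulated optical-phase excursion: a breathing
#' fundamental with harmonics, a weaker ballistocardiographic (cardiac)
#' component with at least one harmonic, slow baseline drift, and white
#' phase noise. Breathing moves the chest far more than the heartbeat does,
#' so by default the cardiac fundamental is a quarter of the breathing
#' amplitude.
#'
#' @param rr_bpm Breathing rate, breaths/min. Must be less than `hr_bpm`.
#' @param hr_bpm Heart rate, beats/min.
#' @param breath_amp_rad Breathing fundamental phase amplitude, rad.
#' @param breath_harmonics Relative amplitudes (to the breathing fundamental)
#'   of the 2nd, 3rd, ... breathing harmonics.
#' @param cardiac_amp_rad Cardiac fundamental amplitude, rad.
#' @param cardiac_harmonics Relative amplitudes of cardiac harmonics; at
#'   least one entry must be positive (the HR rule requires a harmonic).
#' @param drift_amp_rad,drift_freq_hz Slow baseline wander (single
#'   sinusoid; `drift_freq_hz` should stay well below the 0.5 Hz analysis
#'   floor).
#' @param noise_sd_rad Standard deviation of additive white Gaussian phase
#'   noise, rad.
#' @return An object of class `physio_params`.
#' @export
physio_params <- function(rr_bpm = 77, hr_bpm = 158,
                          breath_amp_rad = 6,
                          breath_harmonics = c(0.3, 0.1),
                          cardiac_amp_rad = 0.25 * breath_amp_rad,
                          cardiac_harmonics = 0.4,
                          drift_amp_rad = 2, drift_freq_hz = 0.05,
                          noise_sd_rad = 0.02) {
  amps <- c(breath_amp_rad, breath_harmonics, cardiac_amp_rad,
            cardiac_harmonics, drift_amp_rad, noise_sd_rad)
  if (any(!is.finite(amps)) || any(amps < 0))
    fv_stop("synth", "invalid-params", "all amplitudes must be finite and >= 0")
  if (!is.finite(rr_bpm) || !is.finite(hr_bpm) || rr_bpm <= 0 || hr_bpm <= 0)
    fv_stop("synth", "invalid-params", "rr_bpm and hr_bpm must be positive")
  if (rr_bpm >= hr_bpm)
    fv_stop("synth", "invalid-params",
            sprintf("rr_bpm (%g) must be < hr_bpm (%g)", rr_bpm, hr_bpm))
  if (cardiac_amp_rad > 0 && length(cardiac_harmonics) &&
      all(cardiac_harmonics <= 0))
    fv_stop("synth", "invalid-params",
            "at least one cardiac harmonic amplitude must be > 0")
  structure(list(rr_bpm = rr_bpm, hr_bpm = hr_bpm,
                 breath_amp_rad = breath_amp_rad,
                 breath_harmonics = as.numeric(breath_harmonics),
                 cardiac_amp_rad = cardiac_amp_rad,
                 cardiac_harmonics = as.numeric(cardiac_harmonics),
                 drift_amp_rad = drift_amp_rad,
                 drift_freq_hz = drift_freq_hz,
                 noise_sd_rad = noise_sd_rad),
            class = "physio_params")
}

#' 3x3 coupler channel parameters
#'
#' Per-channel mean intensities `C`, modulation amplitudes `A` and phase
#' asymmetries `delta` of the three coupler outputs
#' `u_k = C_k + A_k * cos(phase + 2*pi*k/3 + delta_k)`, plus additive
#' detector noise. The ideal coupler is `C = 0, A = 1, delta = 0`.
#'
#' @param C Length-3 vector of channel offsets (intensity units).
#' @param A Length-3 vector of channel amplitudes; all must be positive.
#' @param delta Length-3 vector of phase asymmetries, rad.
#' @param detector_noise_sd Standard deviation of additive white detector
#'   noise (intensity units).
#' @return An object of class `coupler_params`.
#' @export
coupler_params <- function(C = c(0, 0, 0), A = c(1, 1, 1),
                           delta = c(0, 0, 0), detector_noise_sd = 0) {
  if (length(C) != 3L || length(A) != 3L || length(delta) != 3L)
    fv_stop("synth", "invalid-params", "C, A and delta must have length 3")
  if (any(!is.finite(c(C, A, delta, detector_noise_sd))))
    fv_stop("synth", "invalid-params", "coupler parameters must be finite")
  if (any(A <= 0))
    fv_stop("synth", "invalid-params", "channel amplitudes A must be > 0")
  if (detector_noise_sd < 0)
    fv_stop("synth", "invalid-params", "detector_noise_sd must be >= 0")
  structure(list(C = as.numeric(C), A = as.numeric(A),
                 delta = as.numeric(delta),
                 detector_noise_sd = detector_noise_sd),
            class = "coupler_params")
}

#' Motion-artifact specification
#'
#' A transient phase disturbance emulating spontaneous subject movement:
#' either a sustained baseline `step` or a raised-cosine `burst` confined
#' to `[onset_s, onset_s + duration_s]`.
#'
#' @param onset_s Onset time, s.
#' @param duration_s Duration, s.
#' @param magnitude_rad Peak phase excursion, rad (>= 0).
#' @param shape `"step"` or `"burst"`.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(onset_s, duration_s, magnitude_rad,
                          shape = c("burst", "step")) {
  shape <- match.arg(shape)
  if (!is.finite(onset_s) || !is.finite(duration_s) || duration_s < 0)
    fv_stop("synth", "invalid-params", "onset_s/duration_s must be finite")
  if (!is.finite(magnitude_rad) || magnitude_rad < 0)
    fv_stop("synth", "invalid-params", "magnitude_rad must be >= 0")
  structure(list(onset_s = onset_s, duration_s = duration_s,
                 magnitude_rad = magnitude_rad, shape = shape),
            class = "artifact_spec")
}

#' Uniformly sampled phase series
#'
#' Container for the optical path length difference expressed as a phase in
#' radians, the quantity the demodulator recovers.
#'
#' @param values Numeric vector of phase samples, rad. Must be finite.
#' @param fs Sampling rate, Hz.
#' @param t0 Start time, s.
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(values, fs, t0 = 0) {
  if (!is.numeric(values) || any(!is.finite(values)))
    fv_stop("synth", "invalid-params", "phase values must be finite numeric")
  if (!is.finite(fs) || fs <= 0)
    fv_stop("synth", "invalid-params", "fs must be positive")
  structure(list(values = as.numeric(values), fs = fs, t0 = t0),
            class = "phase_series")
}

#' Three-channel coupler record
#'
#' Raw sensor output: the three photodetector time series on one time base.
#'
#' @param u Numeric matrix with `n` rows and 3 columns (`u1`, `u2`, `u3`).
#' @param fs Sampling rate, Hz.
#' @param t0 Start time, s.
#' @return An object of class `coupler_record`.
#' @export
coupler_record <- function(u, fs, t0 = 0) {
  u <- as.matrix(u)
  if (ncol(u) != 3L)
    fv_stop("synth", "invalid-params", "u must have exactly 3 channels")
  if (any(!is.finite(u)))
    fv_stop("synth", "invalid-params", "channel samples must be finite")
  colnames(u) <- c("u1", "u2", "u3")
  structure(list(u = u, fs = fs, t0 = t0), class = "coupler_record")
}

#' Time axis of a phase series or coupler record
#' @param x A `phase_series` or `coupler_record`.
#' @return Numeric vector of sample times, s.
#' @export
time_axis <- function(x) {
  n <- if (inherits(x, "coupler_record")) nrow(x$u) else length(x$values)
  x$t0 + (seq_len(n) - 1L) / x$fs
}

duration_of <- function(x) {
  n <- if (inherits(x, "coupler_record")) nrow(x$u) else length(x$values)
  n / x$fs
}

#' Generate a physiologically structured phase signal
#'
#' Sums a breathing sinusoid at `rr_bpm/60` Hz with its harmonics, a cardiac
#' sinusoid at `hr_bpm/60` Hz with its harmonics, a slow drift sinusoid and
#' white Gaussian phase noise. All deterministic components are zero-phase
#' cosines so that coincident frequencies add constructively.
#'
#' @param p A [physio_params()] object.
#' @param s A [sampling_spec()] object. `fs` must be at least four times the
#'   highest simulated harmonic frequency.
#' @param seed Optional integer seed controlling the noise; identical seeds
#'   give bitwise-identical output.
#' @return A [phase_series()].
#' @examples
#' ph <- make_phase_signal(physio_params(rr_bpm = 77, hr_bpm = 158),
#'                         sampling_spec(250, 60), seed = 1)
#' @export
make_phase_signal <- function(p, s, seed = NULL) {
  stopifnot(inherits(p, "physio_params"), inherits(s, "sampling_spec"))
  f_r <- p$rr_bpm / 60
  f_h <- p$hr_bpm / 60
  f_max <- max(f_r * (1L + length(p$breath_harmonics)),
               f_h * (1L + length(p$cardiac_harmonics)),
               p$drift_freq_hz)
  if (s$fs < 4 * f_max)
    fv_stop("synth", "aliasing",
            sprintf("fs = %g Hz is below 4x the highest harmonic (%g Hz)",
                    s$fs, f_max))
  t <- (seq_len(s$n) - 1L) / s$fs
  x <- numeric(s$n)
  add_tone <- function(x, amp, f) if (amp > 0) x + amp * cos(2 * pi * f * t) else x
  x <- add_tone(x, p$breath_amp_rad, f_r)
  for (j in seq_along(p$breath_harmonics))
    x <- add_tone(x, p$breath_amp_rad * p$breath_harmonics[j], (j + 1) * f_r)
  x <- add_tone(x, p$cardiac_amp_rad, f_h)
  for (j in seq_along(p$cardiac_harmonics))
    x <- add_tone(x, p$cardiac_amp_rad * p$cardiac_harmonics[j], (j + 1) * f_h)
  x <- add_tone(x, p$drift_amp_rad, p$drift_freq_hz)
  if (p$noise_sd_rad > 0)
    x <- x + with_seed(seed, stats::rnorm(s$n, sd = p$noise_sd_rad))
  phase_series(x, fs = s$fs, t0 = 0)
}

#' Inject a motion-artifact transient into a phase signal
#'
#' @param phase A [phase_series()].
#' @param a An [artifact_spec()]. Must lie within the record.
#' @return A copy of `phase` with the transient added. For `shape = "burst"`
#'   samples outside `[onset_s, onset_s + duration_s]` are unchanged; for
#'   `shape = "step"` every sample at or after `onset_s` is raised by
#'   `magnitude_rad`.
#' @export
inject_motion_artifact <- function(phase, a) {
  stopifnot(inherits(phase, "phase_series"), inherits(a, "artifact_spec"))
  t <- time_axis(phase)
  t_end <- phase$t0 + duration_of(phase)
  if (a$onset_s < phase$t0 || a$onset_s + a$duration_s > t_end)
    fv_stop("synth", "range-error",
            sprintf("artifact [%g, %g] s outside record [%g, %g] s",
                    a$onset_s, a$onset_s + a$duration_s, phase$t0, t_end))
  x <- phase$values
  if (a$shape == "step") {
    x[t >= a$onset_s] <- x[t >= a$onset_s] + a$magnitude_rad
  } else {
    sel <- t >= a$onset_s & t <= a$onset_s + a$duration_s
    if (any(sel) && a$duration_s > 0) {
      u <- (t[sel] - a$onset_s) / a$duration_s
      x[sel] <- x[sel] + a$magnitude_rad * 0.5 * (1 - cos(2 * pi * u))
    }
  }
  phase_series(x, phase$fs, phase$t0)
}

#' Synthesize the three coupler outputs for a phase signal
#'
#' Applies the interferometric transfer of a 3x3 fiber coupler with uniform
#' split ratio: `u_k = C_k + A_k * cos(phase + (2*pi/3)*k + delta_k)` for
#' `k = 1, 2, 3`, plus optional white detector noise.
#'
#' @param phase A [phase_series()].
#' @param c A [coupler_params()] object.
#' @param seed Optional integer seed for the detector noise.
#' @return A [coupler_record()].
#' @export
make_coupler_record <- function(phase, c = coupler_params(), seed = NULL) {
  stopifnot(inherits(phase, "phase_series"), inherits(c, "coupler_params"))
  n <- length(phase$values)
  u <- vapply(1:3, function(k) {
    c$C[k] + c$A[k] * cos(phase$values + (2 * pi / 3) * k + c$delta[k])
  }, numeric(n))
  if (c$detector_noise_sd > 0)
    u <- u + with_seed(seed,
      matrix(stats::rnorm(3L * n, sd = c$detector_noise_sd), ncol = 3L))
  coupler_record(u, fs = phase$fs, t0 = phase$t0)
}

#' Simulate a paired reference-vs-pad cohort
#'
#' Emulates the study design used to validate the pad: each subject
#' contributes three per-minute paired (reference, pad) values for each
#' vital. The reference equals the per-minute truth; the pad value is the
#' truth plus Gaussian error. Sex and body weight are drawn reproducibly
#' from the seed (female proportion and weight range follow a small
#' neonate-model cohort).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param truth_rr_range,truth_hr_range Integer ranges (length-2) the
#'   per-minute true RR / HR values are drawn from, per-minute units.
#' @param efos_noise_sd Standard deviation of the pad measurement error,
#'   per-minute units.
#' @param n_pairs Paired measurements per subject and vital.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A `paired_measurements` data frame in long format with columns
#'   `subject`, `sex`, `weight_kg`, `vital`, `minute`, `reference`, `efos`.
#' @examples
#' head(make_paired_dataset(5, seed = 1))
#' @export
make_paired_dataset <- function(n_subjects = 29,
                                truth_rr_range = c(39, 129),
                                truth_hr_range = c(122, 202),
                                efos_noise_sd = 2,
                                n_pairs = 3,
                                seed = NULL) {
  if (!is.finite(n_subjects) || n_subjects < 2)
    fv_stop("synth", "insufficient-data", "need at least 2 subjects")
  if (diff(range(truth_rr_range)) <= 0 || diff(range(truth_hr_range)) <= 0)
    fv_stop("synth", "invalid-params", "truth ranges must be non-degenerate")
  if (efos_noise_sd < 0)
    fv_stop("synth", "invalid-params", "efos_noise_sd must be >= 0")
  n_subjects <- as.integer(n_subjects)
  with_seed(seed, {
    sex <- sample(c("F", "M"), n_subjects, replace = TRUE,
                  prob = c(10 / 29, 19 / 29))
    weight <- round(stats::runif(n_subjects, 1.5, 4.15), 2)
    one_vital <- function(vital, rng) {
      truth <- sample(seq(rng[1], rng[2]), n_subjects * n_pairs,
                      replace = TRUE)
      err <- if (efos_noise_sd > 0)
        stats::rnorm(n_subjects * n_pairs, sd = efos_noise_sd) else 0
      data.frame(
        subject = rep(seq_len(n_subjects), each = n_pairs),
        sex = rep(sex, each = n_pairs),
        weight_kg = rep(weight, each = n_pairs),
        vital = vital,
        minute = rep(seq_len(n_pairs), times = n_subjects),
        reference = truth,
        efos = truth + err,
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(one_vital("RR", truth_rr_range),
                 one_vital("HR", truth_hr_range))
    class(out) <- c("paired_measurements", "data.frame")
    out
  })
}
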