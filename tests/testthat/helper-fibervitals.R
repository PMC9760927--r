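# Shared builders for the test suite. Everything is generated in code;
# "noise-free" means zero phase noise and zero detector noise.

clean_physio <- function(rr, hr, ...) {
  physio_params(rr_bpm = rr, hr_bpm = hr, noise_sd_rad = 0, ...)
}

# Noise-free ideal-coupler record at the study defaults (250 Hz, 3 min).
clean_record <- function(rr, hr, duration_s = 180, fs = 250, ...) {
  ph <- make_phase_signal(clean_physio(rr, hr, ...),
                          sampling_spec(fs, duration_s))
  list(phase = ph, record = make_coupler_record(ph))
}

# Build a spectrum_frame directly from (freq, mag) pairs on a 1/length_s
# grid, for unit tests of the extraction rules.
toy_spectrum <- function(peaks_hz, mags, length_s = 60, f_max = 8) {
  res <- 1 / length_s
  freqs <- seq(0, f_max, by = res)
  m <- numeric(length(freqs))
  for (i in seq_along(peaks_hz)) {
    k <- which.min(abs(freqs - peaks_hz[i]))
    m[k] <- mags[i]
  }
  structure(list(freqs = freqs, mags = m, resolution_hz = res,
                 length_s = length_s, distorted = FALSE),
            class = "spectrum_frame")
}

# Independent single-bin DFT magnitudes (plain rectangular DFT, no
# windowing) used as an oracle against the generator and spectra.
raw_dft_peak_freqs <- function(x, fs, n_top = 2) {
  X <- Mod(stats::fft(x - mean(x)))
  half <- floor(length(x) / 2)
  mags <- X[2:(half + 1)]
  ord <- order(mags, decreasing = TRUE)[seq_len(n_top)]
  sort(ord / (length(x) / fs))
}
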