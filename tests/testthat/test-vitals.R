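test_that("RR rule takes the band-limited magnitude maximum", {
  # dominant breathing peak at 77/60 Hz
  sp <- toy_spectrum(c(77 / 60, 2 * 77 / 60), c(6, 1.8))
  rr <- estimate_rr(sp)
  expect_true(rr$valid)
  expect_equal(rr$bpm, 77)
  expect_equal(rr$freq_hz, 77 / 60, tolerance = 1e-12)
  # spectral content only below the 0.5 Hz floor is invalid
  low <- toy_spectrum(0.3, 5)
  expect_false(estimate_rr(low)$valid)
  # argmax, not lowest peak: 1.0 Hz (mag 10) beats 2.0 Hz (mag 4)
  two <- toy_spectrum(c(1.0, 2.0), c(10, 4))
  expect_equal(estimate_rr(two)$bpm, 60)
  # content just above the 2.5 Hz cap is ignored
  capped <- toy_spectrum(c(1.0, 2.6), c(2, 9))
  expect_equal(estimate_rr(capped)$bpm, 60)
})

test_that("harmonic presence detection follows the 2*f0 rule", {
  sp <- toy_spectrum(c(158 / 60, 2 * 158 / 60), c(1.5, 0.6))
  expect_true(has_harmonic(sp, 158 / 60))
  # a lone peak has no harmonic
  expect_false(has_harmonic(toy_spectrum(2.0, 5), 2.0))
  # a harmonic below the relative-amplitude threshold does not count
  weak <- toy_spectrum(c(2.0, 4.0), c(5, 0.2))   # 4% < 5% floor
  expect_false(has_harmonic(weak, 2.0))
  # a harmonic beyond Nyquist cannot be found
  expect_false(has_harmonic(toy_spectrum(5.0, 5, f_max = 8), 5.0))
})

test_that("HR rule takes the lowest harmonic-bearing maximum above the floor", {
  # breathing 77/min; cardiac 158/min with harmonic
  sp <- toy_spectrum(c(77 / 60, 154 / 60, 158 / 60, 316 / 60),
                     c(6, 1.8, 1.5, 0.6))
  hr <- estimate_hr(sp, 77 / 60)
  expect_true(hr$valid)
  expect_equal(hr$bpm, 158)
  # a larger harmonic-free peak below the true HR is passed over
  sp2 <- toy_spectrum(c(1.7, 2.5, 5.0), c(4, 2, 0.5))
  expect_equal(estimate_hr(sp2, 1.0)$bpm, 150)
  # RR >= 1.5 Hz moves the search start to RR + 0.25 Hz
  sp3 <- toy_spectrum(c(1.6, 1.7, 3.4, 2.5, 5.0), c(6, 3, 0.9, 2, 0.5))
  hr3 <- estimate_hr(sp3, 1.6)
  expect_equal(hr3$bpm, 150)   # the 1.7 Hz peak sits below 1.85 Hz
  # no qualifying candidate yields an invalid estimate
  expect_false(estimate_hr(toy_spectrum(c(1.0, 2.0), c(6, 1)), 1.0)$valid)
})

test_that("motion artifacts are flagged per minute by the phase-slope RMS", {
  sim <- clean_record(60, 120)
  ph <- recover_phase(sim$record)
  expect_false(any(vapply(1:3, function(m) detect_distortion(ph, m),
                          logical(1))))
  # a 50 rad step in minute 2 trips the detector there
  stepped <- inject_motion_artifact(sim$phase, artifact_spec(90, 0, 50, "step"))
  expect_true(detect_distortion(stepped, 2))
  expect_false(detect_distortion(stepped, 1))
  # an infinite threshold disables flagging entirely
  expect_false(detect_distortion(stepped, 2, threshold_k = Inf))
  expect_error(detect_distortion(ph, 7), class = "fibervitals_range-error")
})

test_that("pipeline recovers simulation truth on clean default records", {
  sim <- clean_record(77, 158)
  vt <- run_pipeline(sim$record)
  expect_equal(nrow(vt), 3)
  expect_true(all(vt$valid_rr) && all(vt$valid_hr))
  expect_false(any(vt$distorted))
  expect_equal(vt$rr_bpm, rep(77, 3))
  expect_equal(vt$hr_bpm, rep(158, 3))
  expect_error(run_pipeline(clean_record(77, 158, duration_s = 45)$record),
               class = "fibervitals_insufficient-length")
})

test_that("a fully corrupted minute is masked, the others survive", {
  sim <- clean_record(77, 158)
  # two sharp 2000 rad body-movement transients leave minute 2 with no
  # clean 30 s stretch
  hit <- inject_motion_artifact(sim$phase, artifact_spec(70, 2, 2000, "burst"))
  hit <- inject_motion_artifact(hit, artifact_spec(100, 2, 2000, "burst"))
  vt <- run_pipeline(make_coupler_record(hit))
  expect_equal(nrow(vt), 3)
  expect_true(vt$distorted[2])
  expect_false(vt$valid_rr[2] || vt$valid_hr[2])
  expect_true(all(vt$valid_rr[c(1, 3)]) && all(vt$valid_hr[c(1, 3)]))
  expect_equal(vt$rr_bpm[c(1, 3)], c(77, 77))
  expect_equal(vt$hr_bpm[c(1, 3)], c(158, 158))
})

test_that("noise-free recovery is exact across the physiological grid", {
  # resolvable (rr, hr) pairs: the cardiac fundamental must sit at least
  # two bins away from the breathing second harmonic
  set.seed(404)
  pairs <- unique(t(replicate(40, {
    rr <- sample(39:129, 1)
    hr <- sample(max(101, rr + 20):224, 1)
    c(rr, hr)
  })))
  pairs <- pairs[abs(pairs[, 2] - 2 * pairs[, 1]) >= 2, , drop = FALSE]
  pairs <- pairs[seq_len(min(20, nrow(pairs))), , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    rr <- pairs[i, 1]; hr <- pairs[i, 2]
    vt <- run_pipeline(clean_record(rr, hr)$record)
    expect_equal(vt$rr_bpm, rep(rr, 3), info = sprintf("rr=%d hr=%d", rr, hr))
    expect_equal(vt$hr_bpm, rep(hr, 3), info = sprintf("rr=%d hr=%d", rr, hr))
    # band compliance
    expect_true(all(vt$rr_freq_hz > 0.5 & vt$rr_freq_hz <= 2.5))
    if (rr / 60 >= 1.5) expect_true(all(vt$hr_freq_hz > vt$rr_freq_hz))
  }
})

test_that("a heartbeat one bin from twice the breathing rate is unresolvable", {
  # hr = 2*rr - 1: cardiac fundamental and breathing second harmonic merge
  # into one spectral lobe at the 60 s resolution; the rule then cannot
  # report the true HR (it returns the merged neighbour or nothing)
  vt <- run_pipeline(clean_record(60, 119)$record)
  expect_equal(vt$rr_bpm, rep(60, 3))
  expect_true(all(!vt$valid_hr | vt$hr_bpm != 119))
})

test_that("estimate validity degrades monotonically with artifact strength", {
  sim <- clean_record(77, 158)
  n_valid <- vapply(c(0, 40, 2000), function(mag) {
    hit <- sim$phase
    if (mag > 0) {
      hit <- inject_motion_artifact(hit, artifact_spec(70, 2, mag, "burst"))
      hit <- inject_motion_artifact(hit, artifact_spec(100, 2, mag, "burst"))
    }
    vt <- run_pipeline(make_coupler_record(hit))
    sum(vt$valid_rr) + sum(vt$valid_hr)
  }, numeric(1))
  expect_true(all(diff(n_valid) <= 0))
})
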