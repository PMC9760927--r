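---
title: "Methods: interferometric vital-sign extraction and its validation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interferometric vital-sign extraction and its validation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibervitals)
```

## The sensing model

A fiber-optic sensing pad placed under a subject forms the measuring arm of
an interferometer. Chest-wall motion from breathing, and the much smaller
ballistocardiographic recoil of each heartbeat, strain the fiber and change
the optical path length difference (OPLD) between the measuring and
reference arms. The interferometer converts the OPLD, treated throughout
this package as a phase $\varphi(t)$ in radians, into intensity. With a
3×3 fiber coupler of uniform split ratio the three photodetector outputs
are

$$u_k(t) = C_k + A_k \cos\!\big[\varphi(t) + \tfrac{2\pi}{3}k + \delta_k\big],
\qquad k = 1,2,3,$$

where $C_k$ is the channel's mean intensity, $A_k$ its modulation
amplitude and $\delta_k$ a small coupler phase asymmetry. The 120°
inter-channel offsets are the property passive homodyne demodulation
exploits: after equalizing each channel to $C_k = 0$, $A_k = 1$, the phase
is recovered sample by sample as

$$\hat\varphi(t) = \operatorname{atan2}\!\big(\sqrt{3}\,[u_2 - u_3],\;
u_2 + u_3 - 2u_1\big),$$

then unwrapped by removing $2\pi$ jumps between successive samples. We use
the two-argument arctangent deliberately: a principal-branch arctan folds
half of every fringe and makes unwrapping ambiguous, while `atan2` keeps
the full quadrant. The recovered phase equals the true phase up to a
single additive constant (for an ideal coupler the constant is $-\pi/3$),
which is irrelevant downstream because spectra are computed on mean-removed
frames.

$\delta_k$ is modeled as constant per record and is *not* corrected: no
calibration procedure is part of the method, so its effect is instead
bounded by a robustness test (RMS phase error below 0.05 rad for
$|\delta_k| \le 0.1$ rad and 1% detector noise).

## Synthetic signals: what they emulate and what they do not

The package ships a generator (`make_phase_signal`, `make_coupler_record`)
so every downstream stage is testable without hardware. The phase model is
a sum of zero-phase cosines plus noise:

* breathing fundamental at `rr_bpm`/60 Hz, default amplitude **6 rad**,
  with relative harmonics **(0.3, 0.1)**;
* cardiac fundamental at `hr_bpm`/60 Hz at **0.25×** the breathing
  amplitude, with one relative harmonic **0.4** — breathing is a much
  stronger mechanical phenomenon than the heartbeat, and the HR rule
  requires at least one cardiac harmonic;
* baseline drift: one sinusoid of 2 rad at 0.05 Hz, the simplest structure
  that exercises the 0.5 Hz high-pass behaviour of the band rules;
* white Gaussian phase noise, default sd 0.02 rad (zero for the
  "noise-free" validation scenarios);
* optional motion artifacts: baseline steps or raised-cosine bursts
  (`inject_motion_artifact`).

The 6-rad breathing amplitude makes the phase sweep many fringes per
breath, which is both physically typical for fiber interferometers and
necessary for min/max channel equalization to see full fringes. The
default sampling rate is **250 Hz**: far above every simulated harmonic
(the hardware's multi-kS/s capability adds nothing to the algorithmics)
while keeping a 3-minute record at 45 000 samples.

What the generator does *not* emulate: amplitude modulation of breathing
depth, heart-rate variability within a minute, broadband mechanical
resonances of a real pad, non-white detector noise, or the coupling
between body mass and fringe visibility. Passing the recovery tests
therefore demonstrates correctness of the *signal chain*, not field
performance on real subjects.

## Framing and spectra

Estimates are produced per minute. Each whole minute contributes one
non-overlapping, minute-aligned 60 s frame (overlap is left off as the
simplest choice consistent with per-minute reporting). Frames are
mean-removed, multiplied by a *periodic* (DFT-even) Hamming window
$w[n] = 0.54 - 0.46\cos(2\pi n/N)$ and transformed with a one-sided DFT;
magnitudes are scaled so an on-grid cosine of amplitude $a$ reads $a$ at
its bin. The periodic window is chosen over the symmetric one because its
transform is exactly confined to three bins: on-grid tones then produce no
leakage skirt, which keeps the noise-free validation scenarios honest. The
60 s window gives a resolution of 1/60 Hz — exactly one breath or beat per
minute per bin, so integer per-minute truths sit on the grid and rounding
`60 × f` is exact. Zero-padding is available (`pad` argument) but off by
default.

### Motion artifacts and the 30 s fallback

A second of the record is flagged when the RMS of the per-sample phase
increment over that second exceeds **8×** the record's median per-second
RMS; a minute containing flagged seconds is distorted. A distorted minute
falls back to the first 30 s of its longest clean run (resolution 1/30 Hz)
— the placement within the minute is our stipulation, as is the fallback
rule itself beyond "use 30 s under distortion". A minute with no clean
30 s run is reported with both vitals invalid. The per-second flags are
the primitive (`artifact_seconds`); the per-minute Boolean
(`detect_distortion`) is derived from them, since the 30 s placement needs
sub-minute information.

## The extraction rules

**RR** is the frequency of the global magnitude maximum on (0.5, 2.5] Hz,
times 60, rounded to the nearest integer. Content below 0.5 Hz is drift;
the 2.5 Hz cap reflects the observed physiological ceiling. The estimate
is invalid when the band maximum does not exceed **3×** the median in-band
magnitude — a stipulated floor that refuses to read a breathing rate off a
flat spectrum.

**HR** is searched among the **five** largest local maxima in
$(f_\text{start}, 5.5]$ Hz with
$f_\text{start} = \max(1.5\ \text{Hz},\ f_\text{RR} + 0.25\ \text{Hz when }
f_\text{RR} \ge 1.5\ \text{Hz})$; of these, the lowest frequency that has
at least one harmonic is the HR. The 5.5 Hz ceiling (330 beats/min) is our
choice for the otherwise-open "expected range of valid frequencies",
matching the physiological ceiling of the neonate-sized animal model. The
"five maxima by magnitude" reading (rather than the first five in
frequency order) is likewise stipulated.

A candidate at $f_0$ *has a harmonic* when some local maximum lies within
`harmonic_tol_hz` of $2 f_0$ with magnitude at least 5% of the magnitude
at $f_0$. Two numerical choices here matter and are deliberate:

* **`harmonic_tol_hz` = 0.025 Hz** (1.5 bins at 60 s, floored at 1.5 bins
  for coarser frames). The tolerance must stay near one bin: with a loose
  tolerance (say ±0.1 Hz) the cardiac *harmonic* can validate a nearby
  breathing harmonic instead of the cardiac fundamental — e.g. breathing
  at 60/min puts its second harmonic at 2.0 Hz, and with a heartbeat at
  122/min the cardiac harmonic at 4.067 Hz falls within 0.1 Hz of 4.0 Hz,
  so the loose rule would misread HR as 120.
* **`peak_min_rel_amp` = 0.05**: HR candidates must reach 5% of the
  largest local maximum in the search band. Measured spectra always offer
  five prominent maxima; clean synthetic spectra do not, and without this
  floor the "five maxima" fill up with numerical-floor ripple
  (equalization residue at ~10⁻⁷ rad) whose paired ripples then pass the
  *relative* harmonic check. The floor removes only sub-prominence
  candidates and never affects genuine peaks, whose amplitude ratios are
  orders of magnitude above it.

When both estimates are valid but RR ≥ HR the row is reported unchanged
with a logged message: the inversion is physiologically implausible, but
the algorithm never swaps or censors estimates.

### A genuine resolution limit

When the heart rate lies within one bin (1/min) of twice the breathing
rate, the cardiac fundamental and the breathing second harmonic occupy
adjacent 1/60 Hz bins. No window whose main lobe spans more than one bin
can separate them: the two tones merge into a single spectral lobe, and
the harmonic test then either fails or attributes the lobe to the
breathing harmonic. The exact-recovery sweeps therefore cover the
resolvable domain $|hr - 2\,rr| \ge 2$, and a dedicated test documents the
merged-peak behaviour at $hr = 2\,rr - 1$. This is a property of 60 s
spectral analysis itself, not of this implementation.

## Equalization details

`equalize` estimates $\hat C_k = (\max + \min)/2$ and
$\hat A_k = (\max - \min)/2$ per channel over the full record, which is
exact whenever the phase sweeps at least one full fringe; a robust variant
using the 0.5%/99.5% percentiles is available for records with outliers. A
channel whose peak-to-peak range is below 10% of the largest channel's
range has seen no modulation (subject absent, fiber unloaded) and raises a
degenerate-channel error rather than amplifying noise. At a singular
demodulation sample (numerator and denominator both ≈ 0) the previous
sample's value is emitted and a warning counts the occurrences.

## The statistical battery

Method agreement between a reference monitor and the pad is summarized
without distributional assumptions, on differences oriented
*reference − pad*:

* **Bland–Altman**: median difference, quartiles, and non-parametric
  limits of agreement — the empirical 2.5% and 97.5% quantiles
  (type-7 linear interpolation, the estimator left open by convention).
* **ICC(2,1)**: two-way random-effects, absolute-agreement,
  single-measurement intraclass correlation from the subjects × methods
  mean squares, with the 95% Shrout–Fleiss F-based interval. Absolute
  agreement is the clinically relevant question for two fixed devices.
* **Paired Wilcoxon**: exact by enumeration (subset-sum convolution over
  doubled mid-ranks, so ties are handled exactly) up to 20 non-zero
  differences, normal approximation with tie and continuity corrections
  beyond.
* **Mann–Whitney U** (group comparisons): exact enumeration up to a pooled
  n of 12, tie-corrected normal approximation beyond.
* **Levene's test**, Brown–Forsythe variant (absolute deviations from
  group *medians*), for spread differences.
* **Spearman's rho** with a Fisher-z interval using variance
  $1.06/(n-3)$ and a t-approximation p-value.

Repeated pairs per subject are not independent; `efos_agreement` accepts
them as they stand (`per_subject = FALSE`, mirroring a per-pair analysis)
or collapsed to per-subject medians, and reports which convention was
used.

The synthetic cohort generator (`make_paired_dataset`) mirrors the
validation study design — by default 29 subjects, three paired per-minute
values per vital, true rates uniform on the observed cohort ranges (RR
39–129, HR 122–202 per minute), pad error Gaussian with sd 2 per-minute
units (the scale of the observed median differences), sex drawn at the
cohort's 10:19 female:male proportion and weight uniform on 1.5–4.15 kg.

## Problem sizes and runtime choices

Validation runs use 3-minute records at 250 Hz (45 000 samples), 50-pair
rate sweeps for exact recovery, 1 000 replicate null cohorts for the
Wilcoxon size check, and 200 random fixtures for the limits-of-agreement
ordering property. These sizes make every suite complete in seconds to a
couple of minutes on a single core while keeping Monte-Carlo error well
inside the asserted bands (e.g. a binomial sd of ~0.7 percentage points at
1 000 replicates against a ±2-point acceptance band).

## Known limitations

* Estimates are bin-quantized (1/min at 60 s, 2/min at 30 s frames); no
  sub-bin interpolation is applied by default.
* The HR rule inherits the $hr \approx 2\,rr$ ambiguity described above;
  a real monitor would fuse adjacent minutes or longer windows to resolve
  it.
* OPLD is handled purely in phase units; conversion to mechanical
  displacement (via wavelength and fiber geometry) is out of scope.
* Phase unwrapping assumes per-sample phase changes below π; violent
  motion can alias, which is precisely what the artifact detector flags.
* The agreement battery is validated on fixtures and synthetic cohorts;
  published cohort statistics from real recordings are not reproducible
  without the raw data.
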