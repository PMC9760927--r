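Package: fibervitals
Title: Vital-Sign Extraction from a 3x3-Coupler Fiber-Optic Interferometric Pad
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis chain for non-contact monitoring of
    respiratory rate (RR) and heart rate (HR) with an interferometric
    fiber-optic sensing pad. Generates physiologically structured phase
    signals and the corresponding 3x3 fiber-coupler photodetector outputs,
    recovers the optical path length difference by passive homodyne
    demodulation (channel equalization, quadrant-aware arctangent, phase
    unwrapping), extracts per-minute RR and HR from Hamming-windowed
    magnitude spectra using band-limited maximum and harmonic-presence
    rules, and evaluates method agreement with a non-parametric statistical
    battery (Bland-Altman limits of agreement, ICC(2,1), paired Wilcoxon,
    Mann-Whitney, Brown-Forsythe Levene, Spearman rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    car
Config/testthat/edition: 3
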