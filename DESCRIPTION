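Package: songtrigger
Title: Simulated Real-Time Spectrogram-Triggered Auditory Feedback for Birdsong
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline, sample-accurate simulation of a real-time distorted
    auditory feedback (DAF) apparatus for songbird experiments. Implements
    circular-buffer streaming short-time spectrograms, Pearson-correlation
    template detection of song syllables with an rms amplitude gate and
    self-trigger lockout, contingent acoustic feedback (always, probabilistic,
    or pitch-conditional on an FFT-peak pitch estimate), a synthetic
    Bengalese-finch-like song generator with ground-truth annotations, an
    adaptive virtual bird for long-term pitch-shift experiments, and the
    accompanying evaluation statistics: detection confusion counts against
    annotations, half-difference inter-syllable interval estimation,
    two-sample Kolmogorov-Smirnov tests, and daily pitch summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
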