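Package: beatgrid
Title: Accented Rhythm Enumeration and Ordinal Mixed-Model Analysis of
    Beat-Finding Difficulty
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for constructing and analysing grid-based rhythm
    stimuli used in beat-perception experiments.  Exhaustively
    enumerates 16-position rhythms of nine tones and seven silences,
    assigns temporal (grouping) accents after Povel and Essens,
    classifies patterns by counterevidence on and off the beat, projects
    temporal patterns onto loudness-accented analogues, and assembles
    condition-matched concatenated stimuli with decibel-calibrated onset
    schedules and optional WAV rendering.  Includes a synthetic-rater
    generator for ordinal 1-10 difficulty ratings and a from-scratch
    cumulative-link mixed model (participant random intercept, adaptive
    Gauss-Hermite quadrature) with likelihood-ratio term tests,
    chi-square based eta-squared effect sizes, planned contrasts and
    latent-scale condition estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
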