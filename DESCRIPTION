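Package: notchkit
Title: Tailor-Made Notched Music Training Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Audio processing and trial-design toolkit for tailor-made
    notched music training (TMNMT), a sound therapy for tonal tinnitus.
    Implements the target-condition processing chain (spectral
    equalization, a half-octave notch centered at the individual tinnitus
    frequency, +20 dB edge-band enhancement) and the moving-notch placebo
    filter as short-time Fourier overlap-add processors; the recursive
    two-interval forced-choice tinnitus pitch-matching procedure with
    octave-confusion screening and Cent-domain aggregation; stratified
    permuted-block randomization; noncentral-F power analysis for the
    repeated-measures within-between interaction; and the trial's outcome
    arithmetic (VAS composites, change scores, Morris effect sizes, MCID
    flags, harms tabulation). Includes seeded generators for music-like
    audio, probe signals, simulated forced-choice listeners and two-arm
    outcome tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
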