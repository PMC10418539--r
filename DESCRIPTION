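Package: icspike
Title: Multi-Unit Spike-Train Analysis of Inferior Colliculus Responses to
    Tones, Speech Sounds, and Noise-Burst Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies extracellular multi-unit responses from the auditory
    midbrain (inferior colliculus) to a standard stimulus battery: a 1,296
    condition tone grid (frequency x intensity), consonant-vowel-consonant
    speech sounds, and 10 Hz noise-burst trains.  Provides peri-stimulus time
    histograms, baseline-corrected driven rates over fixed response windows,
    first-spike and peak latencies, frequency receptive-field extraction
    (characteristic frequency, threshold, bandwidths, latencies), vector
    strength for phase locking, a leave-one-out nearest-neighbor spike-timing
    classifier for speech-sound pairs, and nonparametric group comparisons
    (Lilliefors normality gate, Mann-Whitney rank-sum, bootstrap confidence
    intervals of the median).  Includes a seeded inhomogeneous-Poisson
    spike-train simulator that generates two-group cohorts (e.g. a treated
    group with selectively weakened speech-evoked responses) so the complete
    pipeline is testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
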