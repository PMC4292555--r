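Package: ecogwarp
Title: Kinematics-Guided Time-Warped Averaging of ECoG Spectrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Temporal alignment of trial-based electrocorticographic (ECoG)
    spectrograms using dynamic time warping of arm-velocity profiles.
    Reaching movements vary in initiation time, speed and duration across
    trials, so conventional onset-aligned averaging smears movement-related
    spectral components (beta-band desynchronization, gamma-band
    synchronization). The package derives a time-registration path per trial
    by warping its velocity profile onto a reference trial, applies the path
    to the trial's baseline-normalized spectrogram, and averages in the
    registered time base. Includes movement-onset detection and epoching of
    synchronized kinematics, Hamming-window short-time Fourier spectrograms
    with percent-change baseline normalization, a permutation-based
    evaluation of the variance reduction achieved by warping, and a seeded
    synthetic-session generator (kinematics, ECoG, EMG) for end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
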