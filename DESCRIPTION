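Package: sleepbold
Title: Sliding-Window Spectral Analysis of BOLD Oscillations During Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects infra-slow (<0.1 Hz) and faster (>0.1 Hz) oscillations in
    regional fMRI BOLD time series via sliding-window Hamming-tapered FFT
    spectrograms with 1/f aperiodic-trend removal, relates their power time
    courses to EEG sleep-spindle and slow-wave activity, maps per-region
    lead/lag times for oscillation onset and offset at wake-sleep transitions,
    and screens respiratory and cardiac confounds (RETROICOR-style nuisance
    regression, alias-frequency analysis). Ships a seedable multi-modal
    synthetic-data generator (BOLD, EEG, hypnogram, physiology) so the whole
    pipeline is testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
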