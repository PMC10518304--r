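Package: oddballp300
Title: Visual Oddball P300 Simulation and Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates visual oddball EEG sessions with ground-truth P300
    components, runs the standard clinical ERP preprocessing chain
    (zero-phase Butterworth filtering, 50 Hz notch, extended-Infomax ICA
    ocular cleanup, epoching, automatic artifact rejection, epoch
    equalization), measures P300 peak amplitude and latency in the
    300-600 ms window at midline electrodes, and reproduces the group-level
    statistics battery used in MCI-versus-control studies: pooled t-tests,
    chi-square, 2x3x2 mixed-design ANOVA with Bonferroni post-hocs, and
    FDR-corrected brain-behavior correlation matrices. Includes BrainVision
    file input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
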