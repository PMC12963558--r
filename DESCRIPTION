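Package: eegmetrics
Title: EEG Workload and Acceptance Neurometrics with Mixed-Design ANOVA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for neuroergonomic studies comparing interface conditions
    with scalp EEG and questionnaires. Implements individual-alpha-frequency
    (IAF) anchored theta and alpha bands, global field power over channel
    subsets, the frontal-theta/parietal-alpha workload index and the
    right-minus-left frontal alpha approach-withdrawal index; a preprocessing
    chain (Butterworth band-pass, blink-template correction, 1-s epoching,
    amplitude-threshold artifact rejection); Likert composite construction by
    positive-correlation screening; a from-scratch 2x2 mixed repeated-measures
    ANOVA (one within-subject, one between-subject factor) with both classical
    and partial eta squared and Duncan's multiple range post-hoc test; and a
    synthetic-study generator with programmable condition effects so the whole
    pipeline is testable offline, including verification of published ANOVA
    tables from their printed sums of squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
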