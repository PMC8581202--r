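Package: bcidnn
Title: Motor-Imagery EEG Classification with a Deep-Network Feature Map
    and a Large-Margin-Distribution SVM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies two-class motor-imagery EEG trials (left vs right
    hand) with a hybrid model: a small feed-forward neural network acts as
    an explicit kernel map whose output feeds a large-margin-distribution
    support vector machine, a linear SVM with squared-hinge slacks whose
    objective additionally rewards a large mean functional margin. Includes
    zero-phase Butterworth band-pass filtering, epoch extraction for the
    standard 9-s cue-paced trial paradigm, log band-power feature
    extraction for mu/beta event-related desynchronization, a stratified
    half-split and grid-search model-selection protocol, a synthetic
    motor-imagery EEG generator, trial I/O in a portable binary container
    and in the MATLAB v5 layout used by the Graz BCI competition datasets,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
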