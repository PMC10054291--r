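Package: hessgaze
Title: Objective Hess Lancaster Screen Test Analysis from Binocular Gaze Recordings
Version: 0.1.0
Authors@R:
    person("Hessgaze", "Developers", email = "hessgaze@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for an eye-tracker-instrumented Hess Lancaster
    screen test (HLST). Reads 250 Hz binocular gaze recordings of a subject
    traversing the 17-point Hess grid under dissociated (red-green) viewing,
    segments the left-eye-test and right-eye-test events, extracts per-target
    fixation dwells with a dispersion-threshold (I-DT) detector, converts the
    inter-ocular landing-point difference at each target into signed horizontal
    and vertical prismatic deviations (prism diopters, esophoria positive,
    right-eye hyperphoria positive), renders Hess-chart data, and statistically
    compares objective deviations with examiner-annotated subjective templates
    (paired t-tests, Pearson correlation, Lilliefors-corrected
    Kolmogorov-Smirnov normality checks). A synthetic binocular gaze simulator
    with known ground-truth phorias replaces eye-tracker hardware for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
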