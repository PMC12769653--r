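Package: pupilpipe
Title: Pupil-Size Preprocessing and Fixation/AOI Analysis
Version: 0.1.0
Authors@R: person("pupilpipe", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reads EyeLink ASC recordings according to a user-defined
    event-marker grammar, runs a chainable per-trial pupil preprocessing
    pipeline (blink removal, resampling, speed- and z-score-based artifact
    rejection, gaze-position filtering, smoothing, gap interpolation,
    baseline correction), computes robust per-trial diagnostics
    (MAD-based baseline and trace outlier bands, preprocessing summaries,
    trial validation), and provides area-of-interest fixation metrics
    (point-in-polygon assignment, dwell statistics, density maps).
    Includes a synthetic-recording generator with injected ground truth
    for testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
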