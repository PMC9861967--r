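Package: icgemd
Title: Fiducial Point Detection in Impedance Cardiography Signals via
    Empirical Mode Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates the B, C and X fiducial points of the impedance
    cardiography (ICG, dZ/dt) waveform using empirical mode decomposition
    (EMD) and its ensemble variant (EEMD), and derives the standard
    hemodynamic parameters: left-ventricular ejection time, dZ/dt maximum,
    Kubicek stroke volume, heart rate and cardiac output. Includes the
    preprocessing chain (polyphase downsampling, Savitzky-Golay smoothing),
    a synthetic ICG generator with analytic ground-truth annotations, a
    tolerance-based annotation matcher for evaluating delineation accuracy,
    and a command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
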