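Package: vsdmask
Title: Similarity-Masking Analysis of Voltage-Sensitive Dye Imaging Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of voltage-sensitive dye imaging (VSDI)
    detection experiments in primary visual cortex under orientation
    similarity masking. Generates synthetic imaging sessions with ground-truth
    retinotopic and orientation-columnar maps, stimulus-evoked responses,
    correlated noise and camera/cortex motion; provides motion stabilization
    with a separable pixelwise motion model, dF/F normalization, columnar-band
    spatial filtering and flash-response extraction; reliability-weighted
    retinotopic, columnar-axis and 12-channel population template decoders;
    complex population-vector trajectory analysis; signal-detection (d-prime)
    behavioral summaries with inverted-Gaussian masking fits; SVD-based
    cross-experiment pooling, trial-count-weighted correlation with
    entropy-based effective sample size, and flat-versus-Gaussian trend
    selection; and a delayed, orientation-tuned divisive-normalization
    population model that reproduces the biphasic masking dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
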