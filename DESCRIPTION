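Package: synapsemetry
Title: Quantification Pipeline for Presynaptic Imaging and Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for the quantitative analyses used in
    synaptic cell biology: fluorescent puncta and aggregate detection with
    per-particle area and integrated-density statistics, thresholded Pearson
    colocalization with a flipped-channel chance control, line-profile
    peak-to-peak distance distributions with a pixel-shift null,
    center-of-mass separation distances, kymograph-based axonal transport and
    cotransport analysis, electron-microscopy vesicle morphometry and
    stereological volume fractions, evoked-current parameter extraction
    (amplitude, rise time, decay tau, charge, paired-pulse ratio), and a
    normality-gated parametric/nonparametric statistical decision tree.
    A synthetic-data module generates every input class with machine-readable
    ground truth so all stages are testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
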