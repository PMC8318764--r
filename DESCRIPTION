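Package: csmri
Title: Compressed-Sensing MRI Reconstruction and Early Neurological
    Deterioration Analysis for Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for compressed-sensing
    magnetic resonance imaging (CS-MRI) of cerebral ischemic stroke, paired
    with the clinical statistics used to study early neurological
    deterioration (END) after intravenous thrombolysis. Provides piecewise
    constant brain phantoms with stroke-like lesions, k-space undersampling
    masks (variable-density random, radial, Cartesian lines), the linear
    measurement model in explicit-matrix and Fourier-operator form,
    exhaustive spark computation and k-sparse uniqueness certificates,
    total-variation L1 and minimum-variation L2 reconstruction with
    split-Bregman solvers, image quality metrics (PSNR, SSIM), an
    NIHSS-based END classification rule, 2x2 contingency statistics (odds
    ratios, chi-square), logistic regression by IRLS with parameter-recovery
    simulation, and a unified command-line interface with HDF5/CSV/JSON
    serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    png,
    rhdf5,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
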