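Package: carotex
Title: Texture, Shape, Histogram and Morphology Features with Prototype and
    Bayes Classification for Carotid Artery B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts a 63-column feature table (gray-level co-occurrence,
    difference and run-length statistics, neighbourhood gray-tone differences,
    fractal dimension, Fourier power-spectrum sums, Gabor and local binary
    pattern summaries, contour shape descriptors, 32-bin histogram and
    distance-correlogram features, and plaque-morphology descriptors) from
    B-mode carotid artery ultrasound images, selects a discriminant subset by
    a between-class distance criterion gated by principal-component loadings,
    and classifies plaque presence with Gaussian or kernel-density Naive Bayes
    and a dynamically growing learning vector quantization network. Includes a
    layered speckled artery phantom generator with ground-truth plaque masks
    so the whole pipeline can be exercised without clinical data, and a
    confusion-matrix evaluation suite with ROC, gain-chart and Box-Cox
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'core_io.R'
    'classifiers.R'
    'evaluation.R'
    'shape.R'
    'morphology.R'
    'histcorr.R'
    'texture.R'
    'features.R'
    'phantom.R'
    'selection.R'
    'pipeline.R'
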