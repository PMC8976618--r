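Package: gelFeatures
Title: Feature Extraction and Subpattern Classification for Gel-State Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Eigen-decomposition and independent-component feature extraction
    for grayscale images of protein gel states, with a nearest-neighbour
    recognition benchmark. Implements PCA via the small-sample transposed
    covariance trick, Wavelet-PCA on the low-frequency (LL) subband of a
    one-level Daubechies decomposition, FastICA with an intra-/inter-class
    distance feature-evaluation statistic, and Subpattern-ICA: block-wise
    independent component features combined by adaptively weighted
    nearest-neighbour voting. Includes a seeded synthetic generator for
    multi-class gel-state image sets (pore texture, illumination drift,
    occlusion) and a repeated-random-split experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    png,
    tiff,
    MASS,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'image-io.R'
    'pca.R'
    'wavelet.R'
    'ica.R'
    'subpattern.R'
    'classify.R'
    'synthetic.R'
    'persistence.R'
    'cli.R'
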