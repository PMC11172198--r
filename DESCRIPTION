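Package: fdlda
Title: Fuzzy Direct Linear Discriminant Analysis for Near-Infrared Spectral Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Feature extraction and classification of near-infrared (NIR)
    spectra by fuzzy direct linear discriminant analysis (FDLDA), a variant
    of direct LDA in which each training sample's contribution to the
    within- and between-class scatter matrices is weighted by its fuzzy
    class membership raised to a weight exponent m. Includes the complete
    chemometric pipeline around it: spectral preprocessing (standard normal
    variate, multiplicative scatter correction, Savitzky-Golay smoothing,
    mean centring), PCA dimensionality reduction, classical and direct LDA,
    k-nearest-neighbour, extreme-learning-machine and Gaussian naive Bayes
    classifiers, a seeded generator of milk-like synthetic NIR datasets,
    and an experiment driver for preprocessing/parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
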