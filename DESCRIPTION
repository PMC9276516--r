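Package: fcmseg
Title: Fuzzy C-Means Segmentation of Brain MR Images with Neighborhood
    Gray-Difference Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tissue segmentation of grayscale brain magnetic-resonance
    images by fuzzy C-means (FCM) clustering with an optional spatial
    regularization term that weights each pixel's neighborhood by the
    Gaussian kernel of gray-level differences, making the partition
    robust to additive noise.  Cluster centers can be initialized by
    global-best particle swarm optimization (PSO).  Includes the SB
    classification-accuracy and reconstruction-error-rate metrics with
    optimal cluster-label matching, multilevel Otsu thresholding and
    crisp k-means baselines, a synthetic three-tissue brain-phantom
    generator with ground truth, PNG/TIFF/NIfTI image input and output,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
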