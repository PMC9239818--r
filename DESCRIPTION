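Package: dkmseg
Title: Density-Initialized K-Means Segmentation of Grayscale Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tissue-class segmentation of 2-D grayscale brain MRI slices by
    k-means clustering whose initial cluster centers are chosen as data
    objects of high local density (density-peaks style) rather than at
    random, together with a traditional randomly-initialized k-means and a
    flat-kernel mean-shift baseline for comparison. Includes a synthetic
    brain-phantom generator with per-pixel ground-truth labels, a
    segmentation error-rate evaluator with optimal label matching, a
    comparison harness, readers and writers for PNG, PGM and NIfTI-1
    images, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'imageio.R'
    'kmeans.R'
    'density.R'
    'meanshift.R'
    'phantom.R'
    'evaluation.R'
    'segment.R'
    'cli.R'
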