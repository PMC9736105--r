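Package: ripecluster
Title: Unsupervised Maturity Grading and Identification of Fruit Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades fruit maturity from RGB images without labels by
    alternating K-Means clustering of convolutional-network features with
    supervised training of the network on the resulting cluster assignments
    (pseudo-labels). Includes a randomly initialized VGG-style backbone with
    penultimate fully connected layer features, PCA and L2 feature
    preprocessing, a Lloyd/k-means++ clusterer with empty-cluster repair,
    cluster-to-stage naming, confusion-matrix metrics (precision, recall,
    F1, overall accuracy), one-way ANOVA with Duncan's multiple range test
    and compact letter displays for conjoint physical and quality property
    analysis, Grad-CAM heatmaps for model interpretation, and a synthetic
    fruit-image and property-table generator that emulates three maturity
    stages (peel color shift, texture roughening, crack opening, seed
    exposure) for fully reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
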