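Package: kpcaig
Title: Gradient-Based Feature Importance for Kernel PCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Kernel principal component analysis with a data-driven ranking of
    the original features. The importance of a feature is measured by the mean,
    over samples, of the norm of the projection of the kernel's partial
    derivative with respect to that feature onto the leading kernel principal
    axes. Includes Gram-matrix centering and eigendecomposition with
    out-of-sample projection, a grid heuristic for the RBF bandwidth based on
    explained variance, per-variable arrow-field visualization of the gradient
    field on the kernel PCA plot, an unsupervised evaluation harness (k-means
    clustering accuracy, normalized mutual information, silhouette and
    explained-variance curves over nested feature subsets), and a seeded
    generator of clustered synthetic expression-like data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    clue,
    cluster,
    data.table,
    ggplot2,
    jsonlite
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
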