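Package: parevo
Title: Directional Statistics for Phenotypic Change Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies (non)parallel evolution of multivariate phenotypes
    through the geometry of phenotypic change vectors. Provides exact null
    distributions of angles and vector correlations between random directions
    in k-dimensional trait spaces, pairwise angle reports, eigenanalysis of
    inter-lineage correlation and inter-trait cross-product matrices with the
    eigenvalue-dispersion identity, high-dimensional uniformity tests
    (Schott's sum-of-squared-correlations test, the Rayleigh test, and Monte
    Carlo tests of the mean pairwise angle), samplers for uniform, von
    Mises-Fisher, antipodal and girdle distributions on the hypersphere, and
    exploratory ordination tools (biplots, specimen-level bootstrap
    confidence ellipses, k-means clustering of directions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
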