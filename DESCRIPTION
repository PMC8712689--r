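Package: stemhisto
Title: Quantitative Histology of Maize Stem Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tissue segmentation, granulometric cell sizing, stereological
    estimation of tissue cell-wall proportions and multispectral
    autofluorescence pseudospectra for darkfield and fluorescence macro-images
    of whole maize stem cross-sections. Provides mathematical-morphology
    primitives (separable square-structuring-element erosions and dilations,
    alternating sequential filters, grey-level granulometry), a semi-automated
    segmentation workflow producing the seven canonical tissue regions of
    interest, morphological descriptors of rind, parenchyma and vascular
    bundles, cylinder-internode stereology of cell-wall amounts, per-tissue
    11-channel autofluorescence pseudospectra with background subtraction and
    section normalisation, downstream multivariate statistics (PCA, ANOVA
    with Tukey comparisons, channel-wise correlation profiles), and a
    synthetic stem phantom generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
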