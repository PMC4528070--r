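Package: fixelcfe
Title: Connectivity-Based Fixel Enhancement for Fixel-Wise White Matter Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-brain statistical analysis of fibre-population-specific
    ("fixel") measures in crossing-fibre white matter. Builds sparse
    fixel-fixel connectivity matrices from streamline tractograms, performs
    connectivity-based smoothing of fixel data, computes the threshold-free
    connectivity-based fixel enhancement (CFE) statistic, and carries out
    permutation-based family-wise-error inference with the general linear
    model. Includes a synthetic phantom generator (bundles, tractograms,
    fixel grids, test-statistic images) and an AFROC simulation framework
    for evaluating sensitivity and specificity of enhancement parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    RNifti,
    igraph,
    generics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
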