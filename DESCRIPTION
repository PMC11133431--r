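Package: spinpls
Title: Spatial Correspondence of Parcellated Cortical Maps via Spin Tests and Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating a parcel-wise cortical phenotype map (for
    example a map of t-statistics from covariate-adjusted regressions of
    cortical thickness on body-mass index) to annotation maps and matrices
    such as neurotransmitter receptor densities, regional gene expression,
    and meta-analytic cognitive-term activation likelihoods. Implements
    spatially constrained spin permutation nulls on a spherical
    parcellation, Pearson correlation batteries with spin p-values and
    false-discovery-rate control, single-response partial least squares
    with spin-permutation component significance and bootstrap-ratio
    feature reliability, hypergeometric gene-set overrepresentation, and a
    synthetic-data generator that emulates the study inputs so the whole
    pipeline is testable without restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
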