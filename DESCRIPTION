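Package: leukomap
Title: Discriminant Leukocyte Maps from Multicolour Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sample-level discriminant analysis of multicolour flow
    cytometry. Cells from all individuals are pooled into a
    cell-count-balanced principal component "base model" of marker
    co-expression, each individual's cell scores are converted into a
    normalized, Gaussian-smoothed histogram on a shared grid, and the
    vectorized histograms are discriminated between two clinical groups
    by orthogonal partial least squares discriminant analysis (OPLS-DA).
    The predictive weights refold into a leukocyte map that shows which
    cell regions are over- or under-represented in either group.
    Includes multiset centring and scaling that weight individuals (not
    cells) equally, leave-sample-out double cross-validation, a
    synthetic cytometry cohort generator with known ground truth, and a
    minimal FCS 3.0/3.1 reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
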