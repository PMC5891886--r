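Package: stromanet
Title: Differential Epithelium-Stroma Proteomic Correlation Networks from
    RPPA and IHC Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for compartment-resolved proteomic profiling of
    tumor tissue. Quantifies reverse-phase protein array (RPPA) dilution series
    into ssDNA-normalized abundance values with negative-control quality
    screening, classifies cases into high and low epithelium:stroma expression
    ratio groups from ordinal immunohistochemistry scores, builds thresholded
    Spearman correlation networks per ratio group and tissue compartment,
    partitions edges into shared and group-exclusive sets, detects modularity
    subgroups in the resulting differential networks, and compares endpoint
    levels between strata with independent-samples t tests. Includes a seeded
    synthetic cohort generator with planted correlation blocks so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
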