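Package: uptakemva
Title: Multivariate Structure-Property-Uptake Analysis for Copolymer
    Nanoparticle Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multivariate analysis of combinatorial
    (co)polymer nanoparticle libraries made by soap-free emulsion
    polymerization, such as styrene/methyl methacrylate latexes.
    Provides aggregation quality control from paired DLS/SEM diameters,
    a micellar particle-size model predicting diameter from zeta
    potential and molecular weight, standardized principal component
    analysis, multiple linear regression with a relative variable-impact
    metric, a logarithmic cellular-uptake model with R-squared based
    exclusion, and a synthetic-library generator for testing the whole
    pipeline without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
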