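Package: gcea
Title: Generalized Cost-Effectiveness Analysis for Health Benefit Packages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sector-wide generalized cost-effectiveness analysis of
    health interventions. From intervention-level present-value costs and
    healthy life years gained versus a common null scenario, the package
    builds league tables banded by order of magnitude of the average
    cost-effectiveness ratio, stratifies them by delivery platform,
    constructs mathematically optimized expansion paths with strict and
    extended dominance handling, applies per-capita budget constraints, and
    summarises benefit packages as equivalent annual cost per capita under
    differential discounting of costs and health effects. Includes a
    synthetic intervention-set generator with coverage ladders and
    programme-level cost structure, and an exhaustive-enumeration frontier
    oracle for validating the path construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
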