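Package: translocgen
Title: Genetic Diversity, Capture and Differentiation Analysis for
    Conservation Translocations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the genetic consequences of conservation
    translocations from codominant microsatellite genotypes and multi-locus
    MHC presence profiles. Provides unbiased expected heterozygosity,
    hypergeometric rarefaction of allelic richness, Ewens sampling-formula
    theta-K, nucleotide diversity, pooled randomization tests of temporal
    change, a Monte-Carlo genetic-capture rarefaction planner for founder
    numbers, Weir-Cockerham F_ST and Jost's D with permutation tests, a
    Mantel comparison of neutral versus functional structure,
    linkage-disequilibrium effective-population-size estimation, and a
    Wright-Fisher forward simulator of source populations, founder draws
    and post-translocation drift.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
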