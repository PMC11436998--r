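Package: evopot
Title: Evolutionary Potential Assessment and Translocation Planning for
    Range-Edge Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for conservation-genetic assessment of fragmented,
    range-edge populations from SNP and microsatellite genotypes:
    per-locality diversity (observed/expected heterozygosity, inbreeding
    with bootstrap confidence intervals, Hardy-Weinberg tests, rarefied
    allelic richness and private alleles), Weir-Cockerham differentiation
    with isolation-by-distance Mantel tests, discriminant analysis of
    principal components (DAPC) clustering, redundancy-analysis (RDA)
    genotype-environment association with candidate-locus detection and
    individual adaptive categorisation, and a rule-based decision
    framework that ranks donor-recipient locality pairs for translocation
    and supportive breeding. Includes an island-model genotype simulator
    for power analysis and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    geosphere,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
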