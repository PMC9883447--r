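Package: popresolve
Title: Marker Resolution for Population Structure: SNPs Versus Microsatellites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of weakly structured, highly mobile
    species genotyped with both microsatellites and ddRAD-seq SNPs. Implements
    read-depth-aware SNP filtering with an auditable ledger, Nei-Chesser
    diversity statistics with bootstrap confidence intervals, population-specific
    and pairwise Weir-Cockerham F-statistics, hierarchical variance-component
    F-statistics (populations nested in countries), rarefied allelic richness,
    chord-distance trees, Mantel and isolation-by-distance tests, sex-biased
    dispersal assignment indices, genotype PCA, regularized nonnegative matrix
    factorization admixture with masked cross-entropy K selection, a
    SNP-subsampling resolution experiment, and a hierarchical Balding-Nichols
    simulator that generates matched SNP and microsatellite datasets for
    end-to-end testing of the full marker-comparison workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
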