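Package: geaoffset
Title: Spatial Genetic Structure, Genotype-Environment Association and
    Genomic Offset for Landscape Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-genomics analyses of diploid biallelic SNP
    data sampled across environmental gradients: locus filtering, principal
    component analysis, ancestry estimation by masked least-squares matrix
    factorization with cross-validated choice of the number of clusters,
    spatial interpolation of ancestry coefficients, AMOVA, global and
    pairwise F_ST with permutation tests, Mantel tests of isolation by
    distance, redundancy analysis (RDA) and partial RDA with permutation
    tests and forward variable selection, variance partitioning among
    environment, geography and demographic history, detection of candidate
    adaptive loci by three structure-aware genotype-environment association
    methods with a consensus rule, adaptive-index landscapes, temporal and
    spatial genomic offsets with rank-based z-prime standardization against
    the contemporary spatial-offset reference distribution, and donor-site
    suitability mapping for assisted migration.  Includes a synthetic-data
    generator (Balding-Nichols clusters plus logistic environmental clines)
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    geosphere,
    jsonlite,
    yaml,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
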