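Package: divscan
Title: Windowed Population-Genomic Scans, Haplotype-Block Genotyping and
    Geographic Cline Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for contrasting weakly differentiated populations that
    carry large non-recombining haplotype blocks, as found across avian
    migratory divides. Implements Weir-Cockerham F_ST, nucleotide
    diversity, Tajima's D and absolute/net divergence (d_XY, d_A) in
    callable-site-normalised genomic windows; multidimensional-scaling
    genotyping of divergent regions into the three diploid haplotype
    classes (SS, NS, NN); maximum-likelihood sigmoid cline fitting with
    parametric-bootstrap confidence intervals; site-level
    haplotype-frequency/phenotype correlations; and a seeded synthetic-data
    generator with analytically known expectations for every statistic,
    used to validate the estimators end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    mclust,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
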