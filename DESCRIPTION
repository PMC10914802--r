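Package: bsaqtl
Title: Bulked-Segregant QTL Mapping for Autotetraploid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end bulked-segregant analysis (BSA-Seq) toolkit for
    quantitative trait locus (QTL) discovery in autotetraploid biparental
    crosses, motivated by drought-tolerance mapping in starch potato. Computes
    the DRYM drought-tolerance index from starch-yield trials, ranks clones and
    assembles contrasting bulks, filters pooled-sequencing variant calls, scans
    the genome with the tricube-smoothed G' statistic against a robust
    log-normal null, summarizes called QTL intervals against a gene annotation,
    attributes bulk SNPs to their parental origin, applies a two-round
    candidate-SNP selection for targeted genotyping panels, and tests panel
    markers for trait association with Fisher's exact test and Kruskal-Wallis
    with eta-squared effect sizes. A tetrasomic-inheritance simulator generates
    parents, F1 clones, phenotypes, pooled-bulk VCFs, gene annotations and
    panel genotypes so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
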