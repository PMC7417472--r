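Package: bsaqtl
Title: Bulked-Segregant QTL-Seq Genome Scans and Candidate-Gene Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for bulked-segregant analysis (BSA)
    of extreme-phenotype pools from a biparental cross. Computes per-SNP
    SNP-index, delta SNP-index and Euclidean-distance (ED) statistics from
    pooled allele depths, smooths them with tricube sliding windows, derives
    significance thresholds (depth-conditional simulated null bounds for the
    delta SNP-index, robust genome-wide cutoffs for ED), calls candidate
    regions and intersects the two methods' regions. Includes a synthetic
    F2-cross generator (genotypes, phenotypes, extreme bulks, pooled
    binomial read depths) with known truth for end-to-end validation, plus
    post-scan triage utilities: differential-expression classification,
    four-set Venn partitions, gene-interval overlap, region-by-DEG candidate
    filtering, 2^-ddCt relative expression and single-marker genotype ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    tools,
    e1071,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
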