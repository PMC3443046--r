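Package: longampr
Title: Simulation, Alignment and Variant Validation for High-Indel
    Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating single-molecule long-read amplicon data for
    human SNP validation and discovery. Simulates diploid amplicon panels and
    long reads under an indel-dominated error model (~12% insertions, ~2%
    deletions, ~1% mismatches, uniformly distributed along reads), aligns reads
    with an affine-gap glocal dynamic program whose gap-open penalty is lower
    than the mismatch penalty, profiles error modes, read lengths and GC-bias
    coverage curves, performs covariate-based empirical base-quality
    recalibration from a flat Q20 prior, calls diploid SNP genotypes with a
    Bayesian model adapted to high deletion rates, validates call sets against
    truth-status VCFs with confusion-matrix metrics, and quantifies
    alignment-induced reference bias at heterozygous sites, including alternate
    alleles hidden inside insertions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    BiocGenerics,
    jsonlite,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
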