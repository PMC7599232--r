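Package: iterref
Title: Iterative Alternative Reference Construction for Diverged Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds breed-specific alternative reference genomes by iterating
    read mapping, pileup SNP genotyping, and homozygous-allele substitution
    into the reference, so that reads over highly variable regions (runs of
    three or more consecutive mismatches) become mappable round by round.
    Includes a deterministic k-mer seed-and-extend read mapper, a pileup
    genotype caller, callset benchmarking (precision and sensitivity against
    a gold standard), logistic saturation-curve fitting with analytic
    tangent-slope thresholds for choosing the optimal sequencing coverage and
    iteration count, highly-variable-region detection with gene/CDS overlap
    annotation, and a synthetic-data generator that plants background SNPs,
    heterozygous sites, and clustered variable regions in a diverged genome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    minpack.lm,
    Biostrings,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
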