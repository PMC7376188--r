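Package: forenseqr
Title: Sequence-Based STR Allele Nomenclature, Genotyping and Forensic
    Population Statistics for MPS Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns per-sample massively parallel sequencing (MPS) allele
    observations at forensic STR and identity-SNP loci into bracketed
    sequence-based allele names with capillary-electrophoresis (CE)
    designations, quality-controlled genotypes, repeat/flanking variant
    classifications, and forensic population statistics. Implements
    length-anchored CE designation, allele coverage ratio (ACR) thresholded
    genotype calling, counting-method allele frequencies with ploidy-aware
    denominators, gene and haplotype diversity, effective allele number,
    match and exclusion probabilities (RMP, DP, PE, X-chromosomal MEC),
    Hardy-Weinberg and linkage disequilibrium permutation tests with
    Bonferroni correction, log-domain panel combination (CMP, TDP, CPE),
    and a fully seeded synthetic cohort generator so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
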