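Package: demcatalog
Title: Multi-Ancestry Catalog of Coding Variation in Dementia Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: A reusable pipeline for multi-ancestry whole-genome
    characterization of eleven Alzheimer's disease and related dementia
    (AD/ADRD) genes. Implements cohort quality control and relatedness
    pruning (KING-robust kinship, heterozygosity F, exact Hardy-Weinberg
    and differential-missingness tests), variant normalization and
    case-only CADD-based prioritization with known/novel classification,
    APOE epsilon-diplotype calling from rs429358/rs7412 with
    ancestry-stratified frequency tables, a four-model framework
    (protective, conditional, linkage-disequilibrium R2, interaction)
    for protective and resilience variants, gene-level rare-variant
    burden testing via a from-scratch SKAT-O with a permutation oracle,
    and polygenic-risk-score stratified enrichment. Ships a synthetic
    cohort generator and machine-readable transcriptions of the
    published discovery-phase variant catalog so the whole pipeline is
    testable without access-controlled biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
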