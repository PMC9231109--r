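Package: spudprint
Title: SNP Fingerprinting of Tetraploid Potato Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA fingerprinting of tetraploid potato (Solanum
    tuberosum) cultivars with small bi-allelic SNP panels. Covers the full
    workflow: per-marker population statistics (reference-allele frequency,
    minor allele frequency, polymorphism information content) and genotype
    accumulation curves; allele-dosage extraction from tetraploid VCF
    genotypes with read-depth filtering; a filter cascade and greedy selector
    that reduce a large candidate SNP set to a small, well-spaced
    fingerprinting panel; calling of allele dosage (0-4) from two-channel
    KASP endpoint fluorescence with an ordered five-component mixture model
    and assay-failure detection; Kosman allele-dosage distances with
    complete-linkage clustering and Newick export; a genotype database with
    assay-over-sequencing precedence; and forensic-style identity assignment
    with tetraploid random match probabilities under the product rule. A
    population and plate simulator generates realistic synthetic cohorts so
    the whole pipeline is testable without restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
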