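Package: colocnet
Title: Genomic Co-Localization Analysis of Co-Expressed and Co-Interacting Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of the chromosomal co-localization of
    co-expressed and co-interacting genes. For every gene, the likelihood of
    finding its network partners within a +/-W gene-order window is compared
    with its genome-wide partner likelihood, giving a per-gene fold-change
    (FC) that classifies genes as randomly placed (FC about 1) or clustered
    (FC >= 2). The package also computes the decay of co-localization
    likelihood with inter-loci gene-order distance, counts neighborhood
    partner events conserved between two species at identical or mirrored
    gene-order offsets (absorbing segmental inversions), and computes
    pairwise linkage-disequilibrium statistics (D, D', r2) over SNPs
    flanking co-localized genes. Synthetic generators for genomes, networks
    with planted gene clusters, rearranged second species, and phased
    haplotype panels make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
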