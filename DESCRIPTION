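Package: genediv
Title: Candidate-Gene Nucleotide Diversity, Haplotype, Linkage and
    Association Analysis for Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for resequenced candidate-gene amplicons in
    panels of inbred (haploid-equivalent) lines. From a gapped multiple
    sequence alignment and a gene-structure annotation it calls SNPs and
    multi-allelic indel events, computes per-region nucleotide diversity
    (pi, Watterson's theta) and the Tajima's D and Fu and Li's D*/F*
    neutrality tests, collapses full-length and CDS haplotypes with
    haplotype diversity and protein translation, estimates pairwise
    linkage disequilibrium with five LD-decay regression families and
    Hudson-Kaplan minimum recombination events, and tests marker-trait
    association under a population-structure-corrected general linear
    model. A synthetic-data generator emulating a maize starch-gene
    amplicon panel makes every stage testable without external data.
License: MIT
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
    stringr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    withr,
    Biostrings,
    minpack.lm,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
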