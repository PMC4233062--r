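Package: hsfkit
Title: Heat Shock Transcription Factor Gene-Family Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of the plant heat shock
    transcription factor (Hsf) gene family: homolog mining from EST pools by
    six-frame translated homology search and greedy contig assembly, rule-based
    annotation of the Hsf domain architecture (DNA-binding domain, HR-A/B
    heptad repeats, NLS/NES/AHA motifs), A/B/C class and subclass assignment,
    segmental and tandem duplication calling under an 80/80 coverage and
    similarity rule, spliced alignment of coding sequences to genomic loci,
    neighbor-joining phylogenies with Poisson-corrected distances and
    bootstrap support, Nei-Gojobori synonymous and non-synonymous substitution
    counting, and comparative delta-delta-CT quantification of qRT-PCR heat
    shock response patterns. Includes a seeded synthetic-data generator that
    plants machine-readable truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
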