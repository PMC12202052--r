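Package: genarch
Title: Genome Architecture Statistics for Fungal Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for describing the repeat and gene-spacing architecture of
    fungal genome assemblies. Detects perfect simple sequence repeats (SSRs,
    motifs of 2-10 bp repeated at least five times) and summarises their
    density, coverage and canonical motif spectrum per megabase; calls
    telomeric repeat arrays at scaffold termini; computes strand-aware 5' and
    3' flanking intergenic regions (FIRs) from gene models, bins them into
    two-dimensional log-scale density surfaces, classifies genes into
    gene-dense and gene-sparse compartments and tests effector and CAZyme
    enrichment in the sparse compartment with Fisher's exact test and
    Benjamini-Hochberg correction; and bundles the small normalisation
    statistics used in comparative tables (per-10,000-gene rates, coding
    fraction, enzyme activity, protein-cluster summaries). A fully seeded
    synthetic-assembly simulator with ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
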