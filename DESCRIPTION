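Package: gtrnr
Title: Automated Refactoring of Genome-Scale Transcriptional Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the automated redesign of bacterial genome organization
    while preserving the wild-type transcriptomic response to environmental
    change. A genome-scale transcriptional regulatory network (GTRN) is
    modelled with linear ordinary differential equations driven by
    transcription-factor levels and environmental uptake fluxes; candidate
    genomes are scored by expression similarity to the wild type plus an
    operon-entropy modularity term, and the operon structure is rewired by
    Monte Carlo simulated annealing over gene moves and tandem-promoter edits.
    A compiler turns an optimized network into an annotated nucleotide
    sequence (FASTA/GenBank) and parses such sequences back, and a synthetic
    genome generator provides fully self-contained test beds. Analysis
    utilities compute complexity ratios, adaptation optimality degrees,
    operon functional similarity, and regulatory-topology statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
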