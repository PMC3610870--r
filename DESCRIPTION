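Package: nodtx
Title: Primary Transcriptome, Orthology and Repeat Analysis for a
    Cyanobacterial Genome-Transcriptome Study
Version: 0.1.0
Authors@R:
    person("Nodtx", "Maintainers", email = "nodtx@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse a bacterial primary transcriptome from
    differential RNA-seq (dRNA-seq): strand-specific read 5'-end and
    coverage profiles, transcriptional start site (TSS) detection with a
    windowed read-count threshold and a read-through enrichment test,
    positional TSS classification (gTSS/iTSS/aTSS/nTSS) against a gene
    annotation, spaced-dyad promoter motif scanning of the NtcA type
    (GTA-N8-TAC), a comparative-proteome orthology pipeline (HSP merging,
    identity/coverage best-hit filtering, Markov clustering, genome-subset
    categorisation), and direct-repeat excision-element sequence utilities.
    Includes a seeded synthetic-data generator so the whole pipeline is
    testable without external downloads, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
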