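Package: shuffleseq
Title: Simulation and Analysis of Barcoded loxPsym Shuffle-Cassette Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse multiplex structural-variant
    engineering experiments based on randomly integrated, doubly barcoded
    loxPsym "shuffle cassettes". The package generates synthetic experiments
    on a small diploid hybrid genome (cassette integrations at TTAA sites,
    Cre-mediated deletions, inversions, translocations and ecDNA circles,
    and the three read types the assay produces), maps integration sites
    from T7 in vitro transcription reads, calls and classifies
    rearrangements from novel barcode combinations in bulk amplicon data,
    and genotypes structural variants in single cells by reconstructing
    clonotypes from barcode-by-cell count matrices and assigning cells to
    them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
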