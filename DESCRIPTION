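Package: ervtools
Title: Epigenetic Interplay Between Endogenous Retroviruses and Genes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the epigenetic interplay between endogenous
    retrovirus (ERV) insertions and nearby genes in a mammalian genome.
    Implements random-insertion null simulation with depletion-zone detection
    for ERV distances to transcription start/termination sites, DNA
    methylation quantification from MeDIP-qPCR cycle-threshold tables and from
    bisulfite clone sets (with conversion-rate and PCR-duplicate quality
    filters), LTR orientation and CpG-island promoter association statistics,
    methylation-spreading assessment, and orientation-normalized chromatin
    signal profiles over ERV-gene intervening regions. A synthetic-data module
    generates every input the pipeline consumes so all stages are testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    withr,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
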