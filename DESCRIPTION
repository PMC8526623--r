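Package: polkinetics
Title: Pol II Elongation, Pausing and mRNA Decay Kinetics from Nascent and
    Metabolic RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying RNA polymerase II transcription kinetics
    and mRNA turnover from sequencing data. Implements spike-in normalized,
    strand-specific signal tracks for PRO-seq and ChIP-seq; promoter and
    gene-body region definitions from TSS atlases and transcript models; a
    leading-edge wave caller that converts DRB-washout PRO-seq time courses
    into per-gene elongation rates and processivity indices; Pol II stalling
    indices, expression filters and binned metagene profiles; SLAM-seq
    half-life estimation by robust regression on linearized exponential
    decay; and a transcript-buffering statistic contrasting steady-state and
    nascent fold changes. A synthetic-data generator with known ground truth
    supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
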