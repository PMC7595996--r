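Package: nucleoguide
Title: Nucleosome-Map-Guided sgRNA Design for dCas9 Transcriptional Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for positioning sgRNAs for dCas9-based transcriptional
    activators (CRISPRa) using genome-wide nucleosome occupancy maps. Converts
    MNase-seq fragment alignments into smoothed per-base occupancy profiles,
    calls nucleosome dyad axes as profile peak maxima and delineates
    nucleosome-free regions by a fixed dyad-axis offset, enumerates NGG-PAM
    protospacers with exhaustive Hamming-distance off-target vetting, ranks
    candidate guides by nucleosome-free-region membership and distance to the
    transcriptional start site (including divergent gene pairs sharing a
    bidirectional promoter and multiplex guide sets), emits ribozyme-flanked
    sgRNA cassette oligonucleotides, and quantifies activation from qPCR Ct
    tables by the 2^-ddCt method. Includes a synthetic-locus simulator with
    planted nucleosome arrays, promoter NFRs and Ct tables for fully
    self-contained validation.
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
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Epigenetics, NucleosomePositioning, CRISPR, Sequencing, Coverage
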