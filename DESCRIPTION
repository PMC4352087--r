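Package: eccFinder
Title: Detection of Extrachromosomal Circular DNA and Tandem Amplification
    from Paired-End Sequencing Evidence
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and characterize extrachromosomal circular DNA
    (eccDNA) and its chromosomal tandem reintegration from paired-end
    short-read evidence. Implements two-sample read-depth log2-ratio copy
    number scanning with moving-average smoothing, soft-clip based breakpoint
    clustering and junction reconstruction with unit-length inference,
    microhomology analysis around breakpoints, and in-silico PCR and
    restriction-digest (Southern) predictions that discriminate locus
    topologies (single copy, deletion, episomal circle, tandem arrays).
    A synthetic-data module builds parameterized diploid genomes carrying an
    amplifiable cassette locus and simulates paired-end reads with exact
    truth alignments, so every stage of the inference chain is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: CopyNumberVariation, StructuralVariation, Sequencing, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'coverage.R'
    'insilico.R'
    'scenario.R'
    'simulate.R'
    'io.R'
    'junction.R'
    'locusModel.R'
    'microhomology.R'
    'topology.R'
    'pipeline.R'
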