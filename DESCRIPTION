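Package: raslPSI
Title: PSI Quantification and Splicing-Regulator Dependence Calling from
    RASL-Seq Ligation Products
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing RASL-Seq (RNA-mediated oligonucleotide
    Annealing, Selection and Ligation with sequencing) assays of cassette-exon
    alternative splicing. Demultiplexes inline sample barcodes, counts long-
    and short-isoform junction probe matches per splicing event, applies a
    minimum-coverage filter, computes percent-spliced-in (PSI) per replicate
    and per condition, and calls splicing events dependent on the splicing
    regulator PSF/SFPQ in PMA-stimulated JSL1 T cells under two published
    decision rules (an absolute delta-PSI rule and a stimulation-response plus
    knockdown-rescue rule). Also classifies TRAP150/THRAP3 antagonism of
    PSF-regulated exons from resting-cell knockdown shifts. Includes a
    synthetic-data generator (probe libraries, negative-binomial read depths,
    binomial isoform splits, barcoded FASTQ emission) so the full pipeline is
    testable without external sequencing data, and ships a curated fixture of
    39 PSF-dependent events with published condition-mean PSI values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: AlternativeSplicing, Sequencing, Transcriptomics, Software
RoxygenNote: 7.3.3
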