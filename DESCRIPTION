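Package: wrkycensus
Title: Genome-Wide Census and Classification of Plant WRKY Transcription
    Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genome-wide annotation of WRKY transcription
    factor families from protein, CDS and genomic sequences: detection of
    WRKY domains (heptapeptide signatures and C2H2/C2HC zinc fingers),
    isoelectric point and molecular weight prediction, classification into
    groups I, II (subgroups IIa-IIe) and III by reconciling domain
    architecture with a neighbor-joining phylogeny against labelled
    reference proteins, positional gene naming, tandem-duplication and
    gene-cluster detection, exon-intron structure inference from
    genomic/CDS pairs, promoter cis-element scanning with IUPAC patterns,
    and relative expression quantification from qPCR Ct tables by the
    2^-ddCt method. A seeded synthetic-family generator with full ground
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
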