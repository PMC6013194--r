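Package: mybcensus
Title: Genome-Wide Census and Classification of MYB-Superfamily Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable, tested pipeline for the genome-wide identification
    and characterization of MYB-superfamily transcription factors in an
    annotated plant proteome. Detects the 50-53 residue MYB repeat with a
    position-specific scoring matrix built from a seed alignment, classifies
    proteins into repeat-architecture subfamilies (MYB-related/1R, R2R3,
    R1R2R3, 4R, atypical), assigns phylogenetic groups by neighbor-joining
    trees with bootstrap and anchor-guided two-stage labelling, discovers
    conserved motifs with a ZOOPS expectation-maximization model, derives
    exon/intron structures and chromosome distributions from GFF3, calls
    ortholog and paralog pairs via reciprocal best hits and Markov
    clustering, profiles physicochemical properties (molecular weight, pI,
    GRAVY, instability index), and quantifies relative expression from qPCR
    Ct tables with the 2^-ddCt model. A synthetic-data generator with known
    ground truth makes every stage verifiable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
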