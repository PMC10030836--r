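Package: methylRM
Title: Restriction-Modification System Inventories from Bacterial Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers strain-level inventories of bacterial restriction-modification
    (RM) systems from annotated genome records and SMRT base-modification motif
    reports. Classifies annotated genes into RM roles (types I-IV), reconstructs
    operon topologies including the four-gene hsdRSMS arrangement with two
    specificity subunits, performs IUPAC degenerate-motif algebra (reverse
    complement, bipartite decomposition, palindromy, genome scanning,
    modification-fraction statistics), assigns methylation motifs to candidate
    enzymes by cross-strain presence/absence concordance, classifies type I
    systems into families IA-IE by global-alignment identity against reference
    proteins with neighbor-joining trees, and dissects HsdS specificity subunits
    into conserved regions and target recognition domains. A fully seeded
    synthetic-data generator plants operons, motifs and alignments with
    machine-readable ground truth so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
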