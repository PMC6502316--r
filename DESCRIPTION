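Package: zfsurvey
Title: Survey of C2H2 Zinc-Finger Protein Families from Proteome Sequences
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rule-based detection and typing of classical C2H2 zinc-finger
    (C2H2-ZF) domains in protein sequences, following the plant-specific
    QALGGH taxonomy (Q, M1-M5, Z1, Z2 and D types), protein-level subfamily
    classification into tandem and dispersed subsets, physicochemical
    statistics (molecular weight, isoelectric point), tandem gene-array
    calling and subgenome/ortholog accounting from synteny tables,
    Nei-Gojobori (NG86) Ka/Ks estimation with Jukes-Cantor correction and
    Ks-based divergence dating, expression clustering of FPKM matrices,
    ortholog expression correlation, and qPCR 2^-ddCt fold changes.
    Includes simulators that plant zinc-finger domains, codon substitutions,
    tandem arrays and expression groups with known ground truth, so every
    stage of the survey is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
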