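Package: paraconserv
Title: Strain-Level Conservation Scoring of Posttranslational
    Modification Sites in Paralogous Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores per-column amino-acid conservation of multi-strain
    protein alignments with five algorithms (Shannon entropy,
    stereochemically sensitive entropy, Jensen-Shannon divergence against
    a BLOSUM62-derived background, a phylogeny-weighted mismatch score,
    and Karlin substitution-matrix normalization), maps residue positions
    between paralogous proteins by Needleman-Wunsch global alignment,
    computes windowed conservation statistics around posttranslational
    modification sites, and tests whether modified sites sit in more
    conserved sequence context than the identical unmodified residue of
    the paralog (paired distribution-mean test, Monte-Carlo paralog
    pairing test, positional chi-square with post hoc standardized
    residuals).  Includes seed-deterministic synthetic-data generators
    for calibration, and annex analyses of kinase-substrate interactions,
    position-weight-matrix kinase assignment, and secondary-structure
    differences from STRIDE assignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
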