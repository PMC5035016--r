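Package: rfftscan
Title: Automated Scoring of Scanned Ruff Figural Fluency Test Protocols
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated pattern-recognition scoring of the Ruff Figural
    Fluency Test (RFFT) from color scans of the protocol sheets. Models the
    five-part board (35 five-dot patterns per part), recognizes respondent
    drawn connections from red-ink pixel evidence by a five-task algorithm
    (active dots, candidate connections, pixel assignment, line
    compatibility, false-positive rejection), encodes each cell as one of
    1023 designs via a 10-bit connection mask, and derives unique-design,
    perseverative-error and procedure-violation counts. Includes a synthetic
    protocol renderer with a hand-drawing noise model for ground-truth
    validation, and rater-agreement statistics: two-way absolute-agreement
    single-measures intraclass correlation, Lin's concordance correlation
    and Bland-Altman limits of agreement, with the multi-rater
    reconciliation rule used for human criterion scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
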