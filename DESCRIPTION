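Package: meropstools
Title: Cleavage-Site Conservation and Holotype-Based Classification for
    Peptidase Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing whether observed protease substrate
    cleavages are likely to be physiological. Builds per-peptidase subsite
    acceptance profiles (Schechter-Berger P4-P4') from collections of known
    cleavages, maps cleavage sites into multiple alignments of substrate
    homologues, classifies every homologue residue at each subsite as
    conserved, an acceptable replacement, an unacceptable replacement or a
    gap, and reports per-subsite mismatch counts with a qualitative call.
    Also implements the companion classification procedures for peptidase
    families: parsing and formatting of MEROPS-style clan, family and
    holotype identifiers, nearest-holotype identifier assignment under a
    40 percent identity rule, near-duplicate merging above 94 percent
    identity with species, gene and tandem-duplicate guards, active-site
    transfer by homology with peptidase versus non-peptidase-homologue
    reclassification, and representative-set selection for large families.
    Deterministic synthetic-data generators make every component testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
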