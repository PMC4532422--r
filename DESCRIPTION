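Package: mitohet
Title: Strand-Confirmed Mitochondrial DNA Heteroplasmy Calling and Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and quantification of low-level point heteroplasmies in
    high-coverage mitochondrial genome sequencing data. Implements a
    strand-confirmed caller operating on per-position, per-strand filtered base
    counts against the revised Cambridge Reference Sequence (rCRS), systematic
    artifact exclusion (recurrent phantom-mutation contexts, strand coverage
    drops, correlated neighbor sites, primer and circular-edge zones),
    Bland-Altman method agreement between Sanger and next-generation sequencing
    with detection-limit substitution, multi-tissue cohort classification of
    germline versus somatic heteroplasmies, and a synthetic-data generator
    emulating two-haplotype mixture dilution experiments and tumor cohorts with
    clonal expansion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
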