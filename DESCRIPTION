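Package: translatome
Title: Polysome-Profiling Translatome Analysis with Codon and Motif Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-abundance analysis of polysome-profiling count data
    with a negative-binomial GLM likelihood-ratio test, integration of total,
    light and heavy polysomal fractions into transcriptional /
    post-transcriptional / mix regulation categories, chi-squared codon-usage
    enrichment against a whole-transcriptome background with wobble-uridine
    (U34) codon annotation, penta-hydrophilic protein motif scanning with exact
    enrichment testing, and ratio utilities for LC-MS nucleoside
    quantification (tRNA modification levels and 13C m+2 isotopologue
    enrichment). Includes a seeded synthetic-data generator producing count
    tables, coding sequences and ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
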