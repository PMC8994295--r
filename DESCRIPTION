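Package: repeatmosaic
Title: Quantification of Tissue-Specific Somatic Instability of Tandem
    Repeats from Fragment Analysis and Small-Pool PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify somatic mosaicism of expanded tandem
    repeats (such as the hexameric CCCTCT repeat of X-linked dystonia
    parkinsonism) from capillary-electrophoresis fragment analysis and
    single-molecule small-pool PCR. Provides sizing calibration against
    repeat-length standards, modal-allele calling, the relative
    peak-height-threshold expansion index, Poisson titration of
    single-molecule dilutions with plate quality control, allele
    classification and cross-tissue contingency tests, and cohort-level
    repeat-length versus age-at-onset statistics including pairwise
    tissue comparisons and z-score heatmap clustering. A synthetic-data
    generator emulating tissue-specific, length-dependent somatic allele
    distributions, PCR stutter and dilution sampling makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
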