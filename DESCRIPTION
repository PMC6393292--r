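Package: okazakir
Title: Strand-Aware Analysis of Okazaki Fragment Termini
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of lagging-strand Okazaki fragment sequencing data:
    strand-aware extraction of fragment 5' and 3' termini, oriented
    meta-profiles of termini around nucleosome dyads and transcription-factor
    binding sites, in-silico nick ligation with end-labeling quantification,
    cross-correlation shift estimation between conditions, 5'/3' end
    decoupling statistics, and fragment-length periodicity. Includes a
    synthetic lagging-strand fragment simulator with full ground truth so
    every stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
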