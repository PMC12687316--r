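Package: venomglyco
Title: Post-Processing of Snake Venom N-Glycoproteome Identifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the N-glycoproteome of snake venoms from
    bottom-up mass-spectrometry identification tables. Parses N-glycan
    composition strings and computes monoisotopic masses and diagnostic oxonium
    ions; scans proteins for N-glycosylation sequons and calls putative
    (formerly) N-glycosylated peptides from deamidation evidence; assembles
    intact glycopeptide records; computes site microheterogeneity ratios,
    sialylation distributions, glycan co-occurrence networks, binary-matrix
    hierarchical clusterings and exclusive set intersections; and includes a
    synthetic-data generator that emulates a multi-venom study with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
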