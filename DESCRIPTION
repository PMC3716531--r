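Package: parsimovr
Title: Event-Pairing Analysis of Developmental Sequence Heterochrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing ranked developmental event sequences across
    taxa with the event-pairing approach: sequences with simultaneity blocks
    are encoded as three-state relative-timing characters, ancestral sequences
    are reconstructed on a user-supplied rooted phylogeny under Fitch
    parsimony with ACCTRAN/DELTRAN resolution, and per-branch heterochronic
    event movements are inferred by exact Parsimov minimal-movement
    enumeration with necessary-movement consensus. Includes life-phase
    summaries (embryonic/larval event counts, pre-metamorphosis molts and
    stages), a simulator of sequence evolution with planted shifts for
    validation, and a small command-line interface. Ships the branchiopod
    27-event catalogue, the Penilia avirostris sequence, and the branchiopod
    reference topology as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
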