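Package: molcontest
Title: Evaluation Toolkit for Small-Molecule Identification Contests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking computational small-molecule identification
    from tandem mass spectrometry, in the style of community contests where
    participants submit scored candidate structures per challenge. Implements
    submission validation and I/O, stereoisomer collapsing on the first InChIKey
    block, tie-averaged ranking of the correct candidate with the round-up rule,
    per-challenge medal assignment and Olympic tallies, Formula 1 and Medal
    scores, relative ranking positions, consensus score fusion with metadata
    scorers (reference counts, database presence, identifier age, retention-time
    prediction), ppm-tolerant spectral cosine similarity with library search and
    similarity-based training/challenge splitting, and a seeded synthetic
    contest generator so the whole pipeline is testable without contest data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
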