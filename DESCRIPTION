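Package: metierid
Title: Metier Identification and Effort Characterization for Multi-Gear Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies fishing metiers (gear x target-species strata, EU DCF
    level-6 style) from haul-level electronic-logbook records and trip-level
    sales notes. Implements value-based target-species attribution, auditable
    quality-control filters, rank-frequency cutoff selection of the important
    metiers, environmental annotation of hauls (season, fishing area, depth
    stratum, sediment), and per-metier statistical characterization with
    guarded chi-square tests, Bonferroni correction, yearly trend regression
    and gridded effort maps. Ships a seeded synthetic-fleet generator that
    emulates a multi-gear coastal fleet so the whole pipeline is testable
    without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
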