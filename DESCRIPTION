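Package: raricount
Title: Rare-Category Point Counting with Effort-Scaled Abundance Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting high-diversity categorical populations with
    highly unequal abundances, such as microfossil assemblages. Supports a
    two-phase counting workflow in which common taxa identified during a full
    count are skipped during a subsequent rare-only count, and their totals are
    re-estimated from full-phase frequencies scaled by the observational effort
    (microscope-slide tracks) spent in each phase. Includes an event-sourced
    counting session with undo and checkpoint/resume, species-accumulation
    (collector's) curves with hyperbolic asymptote fits, closed-form and
    Monte-Carlo rarefaction, binomial error landscapes for choosing exclusion
    cut-offs, a synthetic-assemblage simulator, readers and writers for the
    four-block Stratigraphic Occurrence Data (SOD) tab-text format, and a
    terminal interface for interactive and batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
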