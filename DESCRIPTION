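Package: asrtlearn
Title: Statistical Learning and Rapid Consolidation Analysis for the
    Alternating Serial Reaction Time Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing implicit statistical learning and general
    skill learning in the alternating serial reaction time (ASRT) task:
    probabilistic sequence generation, high/low-probability triplet
    classification, trial- and participant-level quality control,
    unit-of-five-blocks learning scores, online/offline change-score
    decomposition of within-block and between-rest dynamics, process
    dissociation procedure (generation task) scoring against the 25% chance
    level, and a synthetic cohort simulator so the full pipeline is
    exercisable without raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
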