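Package: jointgroups
Title: Joint-Group Structure and Patient Subgroups in 28-Joint Rheumatoid Arthritis Synovitis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise synovitis across the 28 joints used in
    rheumatoid arthritis disease-activity scoring. Computes per-joint affected
    rates with one-assessment-per-patient resampling, tests right-left
    laterality with an exact binomial test, maps pairwise co-occurrence of
    joint symptoms with Cohen's kappa and a principal-component embedding that
    recovers the three joint groups (large and wrist, MCP, PIP), clusters
    patient evaluations into subgroups by Ward's method on group affected
    rates, and relates subgroups to radiographic joint destruction from
    modified Sharp scores. Includes a latent-Gaussian synthetic cohort
    generator with planted archetypes and correlation structure so every
    stage of the pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
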