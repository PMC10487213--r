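Package: solvscreen
Title: Green-Solvent Screening for Seed-Oil Extraction with Hansen
    Solubility Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational screening of bio-based replacement solvents for
    lipid extraction. Implements Hansen solubility parameter (HSP) affinity
    scoring via relative energy difference (RED) numbers, inverse estimation
    of a solute's Hansen sphere (center and interaction radius) from observed
    RED values by bounded multi-start nonlinear least squares, COSMO-RS-style
    relative-solubility normalization and ranking, fatty-acid class indices
    (SFA/MUFA/PUFA and the PUFA/SFA ratio), sterol and tocopherol totals with
    printed-total consistency checks, and a screening report joining in-silico
    and experimental solvent rankings through correlation and rank-concordance
    statistics. Ships reference tables for a sesame seed oil case study and a
    fully seeded synthetic-data generator for every input the pipeline
    consumes.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
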