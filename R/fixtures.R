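# Packaged reference data: a six-solvent sesame seed oil screening case
# study (solvent properties and HSPs, RED matrix, COSMO-RS relative
# solubilities, fatty-acid compositions, sterol/tocopherol contents with
# their published "Total" annotations, phenolic/antioxidant endpoints and
# extraction yields). RED and relative-solubility values are outputs of
# external software, carried here as reference inputs; this package never
# claims to recompute them from molecular structure.

sesame_path <- function(file) {
  system.file("extdata", file, package = "solvscreen", mustWork = TRUE)
}

#' Sesame case-study solvent set
#'
#' Six extraction solvents (n-hexane reference, two bio-based ethers, two
#' terpenes, ethanol) with Hansen parameters (MPa^(1/2)) and physical
#' properties (boiling point, log P, molecular weight, viscosity, resource,
#' CMR classification).
#'
#' @return Tibble, one row per solvent.
#' @export
sesame_solvents <- function() {
  read_solvent_set(sesame_path("sesame_solvents.csv"))
}

#' Sesame case-study RED matrix (long form)
#'
#' Published relative energy difference numbers for the five major oil
#' components (palmitic, oleic and linoleic acids, gamma-tocopherol,
#' beta-sitosterol) in the six solvents.
#'
#' @return Long tibble `solute`, `solvent`, `red`.
#' @export
sesame_red_table <- function() {
  read_red_matrix(sesame_path("sesame_red.csv"))
}

#' Sesame RED matrix classified and ranked
#'
#' @return A `red_screen` tibble ([as_red_screen()] applied to
#'   [sesame_red_table()]).
#' @export
sesame_red_screen <- function() {
  as_red_screen(sesame_red_table())
}

#' Sesame case-study relative solubilities (long form)
#'
#' COSMO-RS-derived log10 relative solubilities, already normalized so the
#' best solvent per solute sits at 0.
#'
#' @return Long tibble `solute`, `solvent`, `log10_x_rel`.
#' @export
sesame_relative_solubility <- function() {
  read_red_matrix(sesame_path("sesame_relative_solubility.csv"),
                  value = "log10_x_rel")
}

#' Sesame case-study fatty-acid profiles (long form)
#'
#' Ten fatty acids (% of total fatty acids) per extraction solvent.
#'
#' @return Long tibble `sample`, `fatty_acid`, `percent`.
#' @export
sesame_fatty_acids <- function() {
  read_composition(sesame_path("sesame_fatty_acids.csv"))
}

#' Published fatty-acid summary rows for the sesame case study
#'
#' The class totals and PUFA/SFA ratio as printed in the source table,
#' kept as annotations for consistency checking against
#' [fatty_acid_class_sums()].
#'
#' @return Long tibble `sample`, `statistic`, `printed`.
#' @export
sesame_fatty_acid_summary <- function() {
  read_composition(sesame_path("sesame_fatty_acid_summary.csv"),
                   analyte = "statistic", value = "printed")
}

#' Sesame case-study sterol and tocopherol contents (long form)
#'
#' @return Long tibble `sample`, `family`, `component`, `content`
#'   (mg/100 g oil).
#' @export
sesame_components <- function() {
  readr::read_csv(sesame_path("sesame_components.csv"),
                  show_col_types = FALSE) |>
    tidyr::pivot_longer(-c("family", "component"), names_to = "sample",
                        values_to = "content") |>
    dplyr::select("sample", "family", "component", "content")
}

#' Published sterol/tocopherol "Total" annotations
#'
#' Several printed totals are known to disagree with the sum of their own
#' printed components; [component_totals()] flags these rather than
#' correcting them.
#'
#' @return Tibble `sample`, `family`, `printed` (mg/100 g oil).
#' @export
sesame_component_totals <- function() {
  readr::read_csv(sesame_path("sesame_component_totals.csv"),
                  show_col_types = FALSE) |>
    tidyr::pivot_longer(-"family", names_to = "sample",
                        values_to = "printed") |>
    dplyr::select("sample", "family", "printed")
}

#' Sesame case-study bioactivity endpoints and extraction yields
#'
#' Total phenolic content and total antioxidant capacity (mg GAE/g),
#' DPPH IC50 and reducing-power EC50 (ug/mL; lower = stronger), and the
#' gravimetric extraction yield (%).
#'
#' @return Tibble, one row per solvent.
#' @export
sesame_bioactivity <- function() {
  readr::read_csv(sesame_path("sesame_bioactivity.csv"),
                  show_col_types = FALSE)
}

#' Sesame bioactivity joined with recomputed composition totals
#'
#' Convenience input for [build_screening_report()]: the bioactivity table
#' with `sterol_total` and `tocopherol_total` columns recomputed from the
#' packaged component contents.
#'
#' @return Tibble, one row per solvent.
#' @export
sesame_bioactivity_joined <- function() {
  totals <- dplyr::bind_rows(
    component_totals(sesame_components(), "sterol"),
    component_totals(sesame_components(), "tocopherol")
  ) |>
    tidyr::pivot_wider(names_from = "family", values_from = "total") |>
    dplyr::rename(solvent = "sample", sterol_total = "sterol",
                  tocopherol_total = "tocopherol")
  dplyr::inner_join(sesame_bioactivity(), totals, by = "solvent")
}

#' Sesame case-study physicochemical quality parameters
#'
#' Acid, peroxide and iodine values, refractive index, K232/K270,
#' chlorophyll and oxidative stability, carried as reference data only
#' (their measurement is a laboratory procedure outside this package).
#'
#' @return Long tibble `sample`, `parameter`, `unit`, `value`.
#' @export
sesame_oil_quality <- function() {
  readr::read_csv(sesame_path("sesame_oil_quality.csv"),
                  show_col_types = FALSE) |>
    tidyr::pivot_longer(-c("parameter", "unit"), names_to = "sample",
                        values_to = "value") |>
    dplyr::select("sample", "parameter", "unit", "value")
}

#' Published composition-activity correlation coefficients
#'
#' The correlation coefficients reported alongside the sesame case study.
#' They are metadata for informational comparison: recomputing Pearson r
#' from the published per-solvent totals does not reproduce them (they were
#' presumably computed on unpublished replicate-level data), so
#' [build_screening_report()] prints both values and their absolute
#' difference rather than asserting agreement.
#'
#' @return Tibble `endpoint`, `driver`, `reported_r`.
#' @export
sesame_reported_correlations <- function() {
  tibble::tribble(
    ~endpoint, ~driver, ~reported_r,
    "tac", "sterol_total", 0.959,
    "tac", "tocopherol_total", 0.841,
    "tac", "tpc", 0.600,
    "dpph_ic50", "sterol_total", -0.913,
    "dpph_ic50", "tocopherol_total", 0.700,
    "dpph_ic50", "tpc", -0.666,
    "frap_ec50", "sterol_total", -0.882,
    "frap_ec50", "tpc", -0.739,
    "frap_ec50", "tocopherol_total", -0.600
  )
}

#' Fatty-acid common names
#'
#' Optional lookup from `"Cx:y"` codes to trivial names; classification in
#' this package is always by code, never by name.
#'
#' @return Tibble `fatty_acid`, `common_name`.
#' @export
fatty_acid_names <- function() {
  tibble::tribble(
    ~fatty_acid, ~common_name,
    "C8:0", "caprylic acid",
    "C14:0", "myristic acid",
    "C16:0", "palmitic acid",
    "C16:1", "palmitoleic acid",
    "C18:0", "stearic acid",
    "C18:1", "oleic acid",
    "C18:2", "linoleic acid",
    "C18:3", "linolenic acid",
    "C20:0", "arachidic acid",
    "C20:1", "eicosenoic acid"
  )
}
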