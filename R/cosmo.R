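# Relative-solubility layer: converts chemical potentials (e.g. COSMO-RS
# output) into log10 relative solubilities, normalizes each solute row so
# the best solvent sits at 0, and ranks solvents per solute. The quantum
# chemistry that produces the chemical potentials is upstream of this
# package; reference tables of its output ship as fixtures.

GAS_CONSTANT <- 8.314 # J/(mol K)

#' Log10 solubility from chemical potentials
#'
#' `log10(x_j) = (mu_pure - mu_solvent - dg_fusion) / (R T ln 10)`:
#' the infinite-dilution solubility of solute j in a solvent, on a base-10
#' log scale, from the chemical potential of the pure compound, its chemical
#' potential at infinite dilution in the solvent, and its free energy of
#' fusion (0 for a liquid at working temperature).
#'
#' @param mu_pure Chemical potential of the pure compound, J/mol.
#' @param mu_solvent Chemical potential at infinite dilution in the solvent,
#'   J/mol.
#' @param dg_fusion Free energy of fusion, J/mol, >= 0. Default 0 (liquid
#'   solute).
#' @param temperature Absolute temperature, K. Default 298.15.
#' @return log10 solubility (dimensionless). Vectorized.
#' @export
log10_solubility <- function(mu_pure, mu_solvent, dg_fusion = 0,
                             temperature = 298.15) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    abort("`temperature` must be finite and > 0 K.",
          class = "solvscreen_invalid_input")
  }
  if (any(!is.finite(dg_fusion)) || any(dg_fusion < 0)) {
    abort("`dg_fusion` must be finite and >= 0.",
          class = "solvscreen_invalid_input")
  }
  if (any(!is.finite(c(mu_pure, mu_solvent)))) {
    abort("Chemical potentials must be finite.",
          class = "solvscreen_invalid_input")
  }
  (mu_pure - mu_solvent - dg_fusion) / (GAS_CONSTANT * temperature * log(10))
}

#' Relative solubility table from chemical-potential records
#'
#' Applies [log10_solubility()] to each record and normalizes each solute's
#' row so the best solvent is at 0.
#'
#' @param records Data frame with columns `solute`, `solvent`, `mu_pure`,
#'   `mu_solvent` and optionally `dg_fusion` (default 0) and `temperature`
#'   (default 298.15 K).
#' @return Long tibble `solute`, `solvent`, `log10_x` (raw),
#'   `log10_x_rel` (normalized, row maximum 0).
#' @export
relative_solubility <- function(records) {
  needed <- c("solute", "solvent", "mu_pure", "mu_solvent")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("`records` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "solvscreen_invalid_input")
  }
  records |>
    dplyr::mutate(
      dg_fusion = if ("dg_fusion" %in% names(records)) .data$dg_fusion else 0,
      temperature = if ("temperature" %in% names(records)) .data$temperature else 298.15,
      log10_x = log10_solubility(.data$mu_pure, .data$mu_solvent,
                                 .data$dg_fusion, .data$temperature)
    ) |>
    dplyr::group_by(.data$solute) |>
    dplyr::mutate(log10_x_rel = normalize_best_to_zero(.data$log10_x)) |>
    dplyr::ungroup() |>
    dplyr::select("solute", "solvent", "log10_x", "log10_x_rel")
}

#' Normalize a log-solubility vector so the best solvent is 0
#'
#' Subtracts the maximum: the best solvent's log10 solubility is set to 0
#' and all others become relative (<= 0). Idempotent and order-preserving.
#'
#' @param x Numeric vector of log10 solubilities, finite, non-empty.
#' @return Numeric vector with maximum exactly 0.
#' @export
normalize_best_to_zero <- function(x) {
  if (length(x) == 0) {
    abort("Cannot normalize an empty row.", class = "solvscreen_empty_input")
  }
  if (any(!is.finite(x))) {
    abort("Log-solubility values must be finite.",
          class = "solvscreen_invalid_input")
  }
  x - max(x)
}

#' Rank solvents by normalized relative solubility
#'
#' Within each solute, solvents are ranked by decreasing relative
#' solubility: the best solvent(s) -- value 0 after normalization -- share
#' rank 1 (ties take the minimum rank of their band; order within a band
#' follows input position).
#'
#' @param table Long tibble with `solute`, `solvent` and a normalized value
#'   column `log10_x_rel` (each solute's maximum must be 0 to within
#'   `tolerance`).
#' @param tolerance Allowed departure of each row maximum from 0.
#' @return The input with a `rank` column added (1 = most soluble).
#' @examples
#' sesame_relative_solubility() |> rank_relative_solubility()
#' @export
rank_relative_solubility <- function(table, tolerance = 1e-9) {
  needed <- c("solute", "solvent", "log10_x_rel")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("`table` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "solvscreen_invalid_input")
  }
  bad <- table |>
    dplyr::summarise(mx = max(.data$log10_x_rel), .by = "solute") |>
    dplyr::filter(abs(.data$mx) > tolerance)
  if (nrow(bad) > 0) {
    abort(sprintf("Rows not normalized (max != 0): %s.",
                  paste(bad$solute, collapse = ", ")),
          class = "solvscreen_not_normalized")
  }
  table |>
    dplyr::group_by(.data$solute) |>
    dplyr::mutate(rank = dplyr::min_rank(-.data$log10_x_rel)) |>
    dplyr::ungroup()
}
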