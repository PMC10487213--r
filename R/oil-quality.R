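# Oil-composition analytics: fatty-acid class indices, sterol/tocopherol
# totals with printed-total consistency checks, extraction yield and
# profile validation.

FA_CODE_PATTERN <- "^C([0-9]+):([0-9]+)$"

#' Classify a fatty-acid code by saturation
#'
#' Parses codes of the form `"C<carbons>:<double bonds>"` (e.g. `"C18:2"`)
#' and classifies by double-bond count: 0 = SFA (saturated), 1 = MUFA
#' (monounsaturated), >= 2 = PUFA (polyunsaturated).
#'
#' @param code Character vector of fatty-acid codes.
#' @return Factor with levels `"SFA"`, `"MUFA"`, `"PUFA"`.
#' @examples
#' classify_fatty_acid(c("C16:0", "C18:1", "C18:2"))
#' @export
classify_fatty_acid <- function(code) {
  ok <- grepl(FA_CODE_PATTERN, code)
  carbons <- suppressWarnings(as.integer(sub(FA_CODE_PATTERN, "\\1", code)))
  ok <- ok & !is.na(carbons) & carbons >= 2
  if (any(!ok)) {
    abort(sprintf("Malformed fatty-acid code(s): %s.",
                  paste(unique(code[!ok]), collapse = ", ")),
          class = "solvscreen_parse_error")
  }
  db <- as.integer(sub(FA_CODE_PATTERN, "\\2", code))
  factor(ifelse(db == 0, "SFA", ifelse(db == 1, "MUFA", "PUFA")),
         levels = c("SFA", "MUFA", "PUFA"))
}

#' Fatty-acid class sums and the PUFA/SFA ratio
#'
#' Aggregates a long fatty-acid table into per-sample class totals
#' (sum of SFA, MUFA and PUFA percentages) and the nutritional PUFA/SFA
#' ratio. Sums are computed at full precision; round for display to match
#' tabulated compositions (conventionally 2 decimals).
#'
#' @param profiles Long data frame with columns `sample`, `fatty_acid`
#'   (codes `"Cx:y"`) and `percent` (% of total fatty acids, >= 0).
#' @return Tibble with one row per sample: `sample`, `sfa`, `mufa`, `pufa`,
#'   `pufa_sfa_ratio` (NA when SFA is 0, where the ratio is undefined).
#' @examples
#' sesame_fatty_acids() |> fatty_acid_class_sums()
#' @export
fatty_acid_class_sums <- function(profiles) {
  needed <- c("sample", "fatty_acid", "percent")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols) > 0) {
    abort(sprintf("`profiles` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "solvscreen_invalid_input")
  }
  if (nrow(profiles) == 0) {
    return(tibble::tibble(sample = character(), sfa = numeric(),
                          mufa = numeric(), pufa = numeric(),
                          pufa_sfa_ratio = numeric()))
  }
  if (any(!is.finite(profiles$percent)) || any(profiles$percent < 0)) {
    abort("All percentages must be finite and >= 0.",
          class = "solvscreen_invalid_input")
  }
  profiles |>
    dplyr::mutate(class = classify_fatty_acid(.data$fatty_acid)) |>
    dplyr::summarise(
      sfa = sum(.data$percent[.data$class == "SFA"]),
      mufa = sum(.data$percent[.data$class == "MUFA"]),
      pufa = sum(.data$percent[.data$class == "PUFA"]),
      .by = "sample"
    ) |>
    dplyr::mutate(pufa_sfa_ratio = ifelse(.data$sfa > 0,
                                          .data$pufa / .data$sfa, NA_real_))
}

#' Validate a fatty-acid composition table
#'
#' Report-based checks: code syntax, non-negative percentages, and sample
#' totals within `100 +/- tolerance` (compositions rarely close exactly on
#' 100 because of rounding and minor unreported peaks).
#'
#' @inheritParams fatty_acid_class_sums
#' @param tolerance Allowed departure of a sample total from 100, in
#'   percentage points (default 3).
#' @return Tibble with one row per sample: `sample`, `total`,
#'   `total_ok`, `n_bad_codes`, `n_negative`, `bad_codes` (list-column) and
#'   overall `valid`.
#' @export
validate_fatty_acid_profile <- function(profiles, tolerance = 3) {
  needed <- c("sample", "fatty_acid", "percent")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols) > 0) {
    abort(sprintf("`profiles` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "solvscreen_invalid_input")
  }
  carbons <- suppressWarnings(as.integer(sub(FA_CODE_PATTERN, "\\1",
                                             profiles$fatty_acid)))
  profiles |>
    dplyr::mutate(
      code_ok = grepl(FA_CODE_PATTERN, .data$fatty_acid) &
        !is.na(carbons) & carbons >= 2,
      negative = is.finite(.data$percent) & .data$percent < 0
    ) |>
    dplyr::summarise(
      total = sum(.data$percent),
      n_bad_codes = sum(!.data$code_ok),
      n_negative = sum(.data$negative),
      bad_codes = list(.data$fatty_acid[!.data$code_ok]),
      .by = "sample"
    ) |>
    dplyr::mutate(
      total_ok = abs(.data$total - 100) <= tolerance,
      valid = .data$total_ok & .data$n_bad_codes == 0 & .data$n_negative == 0
    ) |>
    dplyr::select("sample", "total", "total_ok", "n_bad_codes",
                  "n_negative", "bad_codes", "valid")
}

#' Per-sample component totals with printed-total consistency checks
#'
#' Sums component contents (e.g. individual sterols or tocopherols, in
#' mg/100 g oil) per sample and family. When annotated totals are supplied
#' (e.g. the "Total" row of a published table) they are compared against the
#' recomputed sum with a tolerance; disagreements are flagged, never
#' silently overwritten -- the recomputed value is always reported.
#'
#' @param table Long data frame with columns `sample`, `family`
#'   (`"sterol"` or `"tocopherol"`), `component`, `content` (mg/100 g, >= 0).
#' @param family Which family to total; one of the families present.
#' @param printed_totals Optional data frame `sample`, `family`, `printed`
#'   carrying annotated totals to check against.
#' @param tolerance Allowed |recomputed - printed| before flagging,
#'   mg/100 g (default 2).
#' @return Tibble `sample`, `family`, `total`, and when `printed_totals`
#'   is given also `printed`, `discrepancy`, `consistent`.
#' @examples
#' component_totals(sesame_components(), "sterol",
#'                  printed_totals = sesame_component_totals())
#' @export
component_totals <- function(table, family, printed_totals = NULL,
                             tolerance = 2) {
  needed <- c("sample", "family", "component", "content")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf("`table` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "solvscreen_invalid_input")
  }
  if (!family %in% table$family) {
    abort(sprintf("Unknown component family `%s` (present: %s).", family,
                  paste(unique(table$family), collapse = ", ")),
          class = "solvscreen_invalid_input")
  }
  if (any(!is.finite(table$content)) || any(table$content < 0)) {
    abort("All contents must be finite and >= 0.",
          class = "solvscreen_invalid_input")
  }
  out <- table |>
    dplyr::filter(.data$family == !!family) |>
    dplyr::summarise(total = sum(.data$content), .by = c("sample", "family"))
  if (!is.null(printed_totals)) {
    out <- out |>
      dplyr::left_join(
        dplyr::select(printed_totals, "sample", "family", "printed"),
        by = c("sample", "family")
      ) |>
      dplyr::mutate(
        discrepancy = .data$total - .data$printed,
        consistent = abs(.data$discrepancy) <= tolerance
      )
    flagged <- dplyr::filter(out, !is.na(.data$consistent) & !.data$consistent)
    if (nrow(flagged) > 0) {
      warn(sprintf(
        "Printed %s totals disagree with component sums (|diff| > %g mg/100 g): %s.",
        family, tolerance,
        paste(sprintf("%s (%.2f vs %.4g)", flagged$sample, flagged$total,
                      flagged$printed), collapse = "; ")),
        class = "solvscreen_total_discrepancy")
    }
  }
  out
}

#' Gravimetric extraction yield
#'
#' Crude oil mass as a percentage of the dry seed mass used for extraction.
#'
#' @param mass_oil Mass of crude oil recovered, g, >= 0.
#' @param mass_seeds Mass of dry seeds extracted, g, > 0.
#' @return Yield in % (g oil / 100 g dry seeds). Vectorized.
#' @export
extraction_yield <- function(mass_oil, mass_seeds) {
  if (any(!is.finite(mass_seeds)) || any(mass_seeds <= 0)) {
    abort("`mass_seeds` must be finite and > 0 g.",
          class = "solvscreen_invalid_input")
  }
  if (any(!is.finite(mass_oil)) || any(mass_oil < 0)) {
    abort("`mass_oil` must be finite and >= 0 g.",
          class = "solvscreen_invalid_input")
  }
  100 * mass_oil / mass_seeds
}
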