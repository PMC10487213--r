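# Delimited-text readers/writers for the package's table layouts, and JSON
# report serialization.

#' Read a solvent set from CSV
#'
#' Expects a header row with at least `name, delta_d, delta_p, delta_h`
#' (MPa^(1/2)); extra property columns (boiling point, log P, ...) are kept.
#'
#' @param path CSV file path.
#' @return Tibble validated for unique names and legal HSPs.
#' @export
read_solvent_set <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_hsp_frame(out, c("name", "delta_d", "delta_p", "delta_h"), "solvent set")
  check_hsp(out$delta_d, out$delta_p, out$delta_h, "Solvent HSP")
  out
}

#' Read solute spheres from CSV
#'
#' Same layout as a solvent set plus an `r_spher` column.
#'
#' @param path CSV file path.
#' @return Tibble with `name`, `delta_d`, `delta_p`, `delta_h`, `r_spher`.
#' @export
read_solute_spheres <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_hsp_frame(out, c("name", "delta_d", "delta_p", "delta_h", "r_spher"),
                  "solute spheres")
  out
}

#' Read a score matrix (RED or relative solubility) from wide CSV
#'
#' Wide layout with one row per solvent (first column `solvent`) and one
#' column per solute, as such tables are usually printed.
#'
#' @param path CSV file path.
#' @param value Name for the value column of the long result.
#' @return Long tibble `solute`, `solvent`, `<value>`.
#' @export
read_red_matrix <- function(path, value = "red") {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  if (names(wide)[1] != "solvent") {
    abort("First column of a score matrix must be `solvent`.",
          class = "solvscreen_invalid_input")
  }
  tidyr::pivot_longer(wide, -"solvent", names_to = "solute",
                      values_to = value) |>
    dplyr::select("solute", "solvent", dplyr::all_of(value))
}

#' Write a screening result as a solute x solvent CSV
#'
#' @param screen Long tibble with `solute`, `solvent` and the value column.
#' @param path Output CSV path.
#' @param values Column to spread (default `"red"`).
#' @return Invisibly, `path`.
#' @export
write_red_matrix <- function(screen, path, values = "red") {
  readr::write_csv(red_matrix(screen, values = values), path)
  invisible(path)
}

#' Serialize a screening result to structured JSON
#'
#' Emits values, suitability labels and per-solute ranks, one object per
#' solute keyed by solvent.
#'
#' @param screen A `red_screen` tibble from [screen_solvents()] or
#'   [as_red_screen()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_screen_json <- function(screen, path) {
  by_solute <- split(screen, screen$solute)
  payload <- lapply(by_solute, function(d) {
    list(values = setNames(as.list(d$red), d$solvent),
         labels = setNames(as.list(as.character(d$label)), d$solvent),
         ranks = setNames(as.list(d$rank), d$solvent))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' Serialize a Hansen sphere fit to JSON
#'
#' @param fit A `hansen_sphere_fit`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(sphere = as.list(fit$sphere), objective = fit$objective,
         residual_rms = fit$residual_rms, converged = fit$converged,
         n_starts_used = fit$n_starts_used,
         residuals = fit$residuals),
    path, auto_unbox = TRUE, digits = 12, dataframe = "rows")
  invisible(path)
}

#' Read a composition table from CSV
#'
#' Two layouts: `"wide"` (first column the analyte code/name, one column
#' per sample -- the usual printed layout) and `"long"`
#' (`sample, analyte, value`).
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param analyte Name of the analyte column in the result (default
#'   `"fatty_acid"`).
#' @param value Name of the value column in the result (default
#'   `"percent"`).
#' @return Long tibble `sample`, `<analyte>`, `<value>`.
#' @export
read_composition <- function(path, layout = c("wide", "long"),
                             analyte = "fatty_acid", value = "percent") {
  layout <- match.arg(layout)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (layout == "long") {
    out <- tibble::as_tibble(raw)
    names(out)[1:3] <- c("sample", analyte, value)
    return(out)
  }
  out <- tidyr::pivot_longer(raw, -1, names_to = "sample", values_to = value)
  names(out)[1] <- analyte
  dplyr::select(out, "sample", dplyr::all_of(c(analyte, value)))
}

#' Serialize a screening report to JSON and flat CSV
#'
#' @param report A `screening_report`.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  written <- character()
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(aggregate = report$aggregate,
           solvents = report$solvents,
           correlations = report$correlations,
           concordance = report$concordance,
           unmatched = report$unmatched),
      json_path, auto_unbox = TRUE, digits = 12, dataframe = "rows")
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    readr::write_csv(report$solvents, csv_path)
    written <- c(written, csv_path)
  }
  invisible(written)
}
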