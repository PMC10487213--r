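# Core Hansen solubility parameter (HSP) mathematics.
#
# A solvent or solute is a point (delta_d, delta_p, delta_h) in MPa^(1/2):
# dispersion, polar and hydrogen-bonding components of the cohesive energy
# density. A solute additionally carries a Hansen sphere radius r_spher;
# solvents inside the sphere (RED < 1) are predicted to dissolve it.

check_hsp <- function(delta_d, delta_p, delta_h, what = "HSP") {
  vals <- c(delta_d, delta_p, delta_h)
  if (length(vals) == 0 || !is.numeric(vals)) {
    abort(sprintf("%s components must be numeric.", what), class = "solvscreen_invalid_input")
  }
  if (any(!is.finite(vals))) {
    abort(sprintf("%s components must be finite.", what), class = "solvscreen_invalid_input")
  }
  if (any(vals < 0)) {
    abort(sprintf("%s components must be >= 0 MPa^(1/2).", what),
          class = "solvscreen_invalid_input")
  }
  invisible(TRUE)
}

#' Total (Hildebrand) solubility parameter
#'
#' Collapses the three Hansen components into the total cohesive parameter
#' `sqrt(delta_d^2 + delta_p^2 + delta_h^2)`.
#'
#' @param delta_d,delta_p,delta_h Dispersion, polar and hydrogen-bonding
#'   components, MPa^(1/2). Vectorized; recycled to a common length.
#' @return Numeric vector of total parameters, MPa^(1/2).
#' @examples
#' hsp_total(13.9, 0.1, 0.1) # n-hexane
#' hsp_total(14, 9.1, 15.2)  # ethanol
#' @export
hsp_total <- function(delta_d, delta_p, delta_h) {
  check_hsp(delta_d, delta_p, delta_h)
  sqrt(delta_d^2 + delta_p^2 + delta_h^2)
}

#' Hansen distance between a solute and a solvent
#'
#' Anisotropic distance in Hansen space, with the conventional factor-4
#' weight on the dispersion axis:
#' `sqrt(4 (dd1 - dd2)^2 + (dp1 - dp2)^2 + (dh1 - dh2)^2)`.
#'
#' @param delta_d1,delta_p1,delta_h1 HSP components of the solute (sphere
#'   center), MPa^(1/2).
#' @param delta_d2,delta_p2,delta_h2 HSP components of the solvent, MPa^(1/2).
#' @return Numeric vector of distances (`r_solv`), MPa^(1/2). Symmetric in the
#'   two points and zero iff they coincide.
#' @examples
#' # n-hexane vs 2-methyltetrahydrofuran
#' hansen_distance(13.9, 0.1, 0.1, 15, 4.7, 3.9)
#' @export
hansen_distance <- function(delta_d1, delta_p1, delta_h1,
                            delta_d2, delta_p2, delta_h2) {
  check_hsp(delta_d1, delta_p1, delta_h1, "Solute HSP")
  check_hsp(delta_d2, delta_p2, delta_h2, "Solvent HSP")
  sqrt(4 * (delta_d1 - delta_d2)^2 +
         (delta_p1 - delta_p2)^2 +
         (delta_h1 - delta_h2)^2)
}

#' Relative energy difference (RED) number
#'
#' `RED = r_solv / r_spher`: the Hansen distance of a solvent from the
#' solute's sphere center, scaled by the sphere radius. RED < 1 places the
#' solvent inside the solubility sphere.
#'
#' @param r_solv Hansen distance(s), MPa^(1/2), >= 0.
#' @param r_spher Sphere radius (recycled), MPa^(1/2), > 0.
#' @return Dimensionless RED number(s), >= 0.
#' @export
red_number <- function(r_solv, r_spher) {
  if (any(!is.finite(r_solv)) || any(r_solv < 0)) {
    abort("`r_solv` must be finite and >= 0.", class = "solvscreen_invalid_input")
  }
  if (any(!is.finite(r_spher)) || any(r_spher <= 0)) {
    abort("`r_spher` must be finite and > 0.", class = "solvscreen_invalid_sphere")
  }
  r_solv / r_spher
}

#' Classify a RED number as suitable or unsuitable
#'
#' A suitable solvent has RED strictly less than 1 (inside the Hansen
#' sphere); the boundary RED = 1 is assigned to the unsuitable class.
#'
#' @param red Dimensionless RED number(s), >= 0.
#' @return Factor with levels `"suitable"`, `"unsuitable"`.
#' @examples
#' classify_red(c(0.31, 0.99, 1, 2.94))
#' @export
classify_red <- function(red) {
  if (any(!is.finite(red)) || any(red < 0)) {
    abort("`red` must be finite and >= 0.", class = "solvscreen_invalid_input")
  }
  factor(ifelse(red < 1, "suitable", "unsuitable"),
         levels = c("suitable", "unsuitable"))
}

check_hsp_frame <- function(data, cols, what) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort(sprintf("`%s` must be a non-empty data frame.", what),
          class = "solvscreen_empty_input")
  }
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", what,
                  paste(missing_cols, collapse = ", ")),
          class = "solvscreen_invalid_input")
  }
  if (anyDuplicated(data$name)) {
    dups <- unique(data$name[duplicated(data$name)])
    abort(sprintf("Duplicate identifier(s) in `%s`: %s.", what,
                  paste(dups, collapse = ", ")),
          class = "solvscreen_duplicate_identifier")
  }
  invisible(TRUE)
}

#' Screen solvents against solute Hansen spheres
#'
#' Builds the full solute x solvent RED grid: for every (solute, solvent)
#' pair the Hansen distance from the sphere center is divided by the sphere
#' radius, classified (RED < 1 = suitable) and ranked within each solute
#' (rank 1 = lowest RED; ties broken by solvent input order).
#'
#' @param solvents Data frame with columns `name`, `delta_d`, `delta_p`,
#'   `delta_h` (MPa^(1/2)); extra columns are ignored.
#' @param solutes Data frame with columns `name`, `delta_d`, `delta_p`,
#'   `delta_h`, `r_spher` describing each solute's Hansen sphere.
#' @return A tibble of class `red_screen` with one row per (solute, solvent)
#'   pair and columns `solute`, `solvent`, `r_solv`, `red`, `label`, `rank`.
#' @examples
#' solvents <- sesame_solvents()
#' solutes <- tibble::tibble(name = "triolein-like", delta_d = 16.4,
#'                           delta_p = 3.8, delta_h = 4.3, r_spher = 8)
#' screen_solvents(solvents, solutes)
#' @export
screen_solvents <- function(solvents, solutes) {
  check_hsp_frame(solvents, c("name", "delta_d", "delta_p", "delta_h"), "solvents")
  check_hsp_frame(solutes, c("name", "delta_d", "delta_p", "delta_h", "r_spher"), "solutes")
  check_hsp(solvents$delta_d, solvents$delta_p, solvents$delta_h, "Solvent HSP")
  check_hsp(solutes$delta_d, solutes$delta_p, solutes$delta_h, "Solute HSP")
  if (any(!is.finite(solutes$r_spher)) || any(solutes$r_spher <= 0)) {
    abort("All `r_spher` must be finite and > 0.", class = "solvscreen_invalid_sphere")
  }

  grid <- tidyr::crossing(
    solutes |>
      dplyr::transmute(solute = .data$name,
                       dd_u = .data$delta_d, dp_u = .data$delta_p,
                       dh_u = .data$delta_h, r_spher = .data$r_spher),
    solvents |>
      dplyr::transmute(solvent_idx = dplyr::row_number(),
                       solvent = .data$name,
                       dd_v = .data$delta_d, dp_v = .data$delta_p,
                       dh_v = .data$delta_h)
  )
  out <- grid |>
    dplyr::mutate(
      r_solv = hansen_distance(.data$dd_u, .data$dp_u, .data$dh_u,
                               .data$dd_v, .data$dp_v, .data$dh_v),
      red = red_number(.data$r_solv, .data$r_spher),
      label = classify_red(.data$red)
    ) |>
    dplyr::arrange(match(.data$solute, solutes$name), .data$solvent_idx) |>
    dplyr::group_by(.data$solute) |>
    # row_number() on a sorted-by-input-order frame is a stable rank:
    # ties keep solvent input order
    dplyr::mutate(rank = dplyr::row_number(.data$red)) |>
    dplyr::ungroup() |>
    dplyr::select("solute", "solvent", "r_solv", "red", "label", "rank")
  class(out) <- c("red_screen", class(out))
  out
}

#' Classify and rank an observed RED table
#'
#' Builds a `red_screen` object directly from observed RED numbers (e.g. a
#' published table) when the underlying spheres are not available:
#' suitability labels (RED < 1) and per-solute ranks are added, with ties
#' broken by input order.
#'
#' @param red_table Long tibble with `solute`, `solvent`, `red`.
#' @return A `red_screen` tibble with `label` and `rank` columns added.
#' @examples
#' as_red_screen(sesame_red_table())
#' @export
as_red_screen <- function(red_table) {
  needed <- c("solute", "solvent", "red")
  missing_cols <- setdiff(needed, names(red_table))
  if (length(missing_cols) > 0) {
    abort(sprintf("`red_table` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "solvscreen_invalid_input")
  }
  out <- red_table |>
    dplyr::mutate(label = classify_red(.data$red)) |>
    dplyr::group_by(.data$solute) |>
    dplyr::mutate(rank = dplyr::row_number(.data$red)) |>
    dplyr::ungroup()
  class(out) <- c("red_screen", class(out))
  out
}

#' Reshape a long screening result to a solute x solvent matrix layout
#'
#' @param screen A `red_screen` tibble from [screen_solvents()] or a long
#'   tibble with `solute`, `solvent` and the value column.
#' @param values Which column to spread: `"red"`, `"rank"` or `"label"`.
#' @return A tibble with one row per solute and one column per solvent.
#' @export
red_matrix <- function(screen, values = c("red", "rank", "label")) {
  values <- match.arg(values)
  screen |>
    dplyr::select("solute", "solvent", dplyr::all_of(values)) |>
    tidyr::pivot_wider(names_from = "solvent", values_from = dplyr::all_of(values))
}

#' @export
print.red_screen <- function(x, ...) {
  n_su <- sum(x$label == "suitable")
  cat(sprintf("<red_screen> %d solutes x %d solvents (%d suitable pairs)\n",
              dplyr::n_distinct(x$solute), dplyr::n_distinct(x$solvent), n_su))
  NextMethod()
}

#' Plot a RED screening grid
#'
#' Tile plot of RED numbers, solutes by solvents, with the suitability
#' boundary (RED = 1) marked by the fill midpoint.
#'
#' @param object A `red_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot red_screen
#' @export
autoplot.red_screen <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$solvent, .data$solute, fill = .data$red)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$red)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  midpoint = 1, name = "RED") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "RED screening (RED < 1 = inside the Hansen sphere)")
}
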