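# Inverse Hansen-sphere estimation: recover a solute's sphere center
# (delta_d, delta_p, delta_h) and radius r_spher from an observed RED row
# over solvents with known HSPs. The forward model is
#   RED_j = hansen_distance(center, solvent_j) / r_spher
# and the fit minimizes the sum of squared RED residuals inside a bounded
# box, restarted from a low-discrepancy set of starting points because the
# center/radius trade-off makes the objective non-convex.

#' Default parameter box for Hansen-sphere fitting
#'
#' Bounds bracket the HSP region where lipid-relevant solutes and common
#' extraction solvents live, with margin; an unbounded fit can drift along
#' the RED scale degeneracy (far-away center with a huge radius).
#'
#' @return A list with numeric `lower` and `upper` vectors, each named
#'   `delta_d`, `delta_p`, `delta_h`, `r_spher` (MPa^(1/2)).
#' @export
hansen_fit_bounds <- function() {
  list(lower = c(delta_d = 10, delta_p = 0, delta_h = 0, r_spher = 0.5),
       upper = c(delta_d = 25, delta_p = 20, delta_h = 25, r_spher = 25))
}

# radical-inverse Halton sequence in (0,1)^length(bases); deterministic
halton_points <- function(n, bases = c(2, 3, 5, 7)) {
  radical_inverse <- function(i, base) {
    r <- 0
    f <- 1 / base
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  sapply(bases, function(b) vapply(seq_len(n), radical_inverse, numeric(1), base = b))
}

check_fit_input <- function(data, min_solvents = 5) {
  check_hsp_frame(data, c("name", "delta_d", "delta_p", "delta_h", "red"), "data")
  if (nrow(data) < min_solvents) {
    abort(sprintf(
      "Sphere fitting needs >= %d solvents (4 unknowns); got %d.",
      min_solvents, nrow(data)), class = "solvscreen_underdetermined")
  }
  check_hsp(data$delta_d, data$delta_p, data$delta_h, "Solvent HSP")
  hsps <- data[, c("delta_d", "delta_p", "delta_h")]
  if (nrow(unique(hsps)) == 1) {
    abort("All solvent HSPs are identical; the sphere is not identifiable.",
          class = "solvscreen_rank_deficient")
  }
  if (any(!is.finite(data$red)) || any(data$red <= 0)) {
    abort("All observed RED values must be finite and > 0.",
          class = "solvscreen_invalid_input")
  }
  invisible(TRUE)
}

sphere_residuals <- function(par, data) {
  hansen_distance(par[1], par[2], par[3],
                  data$delta_d, data$delta_p, data$delta_h) / par[4] - data$red
}

#' Fit a Hansen sphere to an observed RED row
#'
#' Least-squares recovery of a solute's sphere center and radius from RED
#' numbers observed over solvents with known HSPs. The objective
#' `sum((RED_pred - RED_obs)^2)` is minimized with bounded
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]) restarted from `n_starts`
#' Halton points spread over the parameter box; the best terminal objective
#' wins.
#'
#' @param data Data frame with one row per solvent: columns `name`,
#'   `delta_d`, `delta_p`, `delta_h` (MPa^(1/2)) and `red` (observed,
#'   dimensionless, > 0). At least 5 solvents in general position.
#' @param n_starts Number of multistart points (default 16).
#' @param bounds Parameter box, as returned by [hansen_fit_bounds()].
#' @param solute Optional solute name carried into the result.
#' @return An object of class `hansen_sphere_fit`: the fitted `sphere`
#'   (tibble: `name`, `delta_d`, `delta_p`, `delta_h`, `r_spher`), the
#'   per-solvent `residuals` tibble (observed, predicted, residual),
#'   `objective` (sum of squares), `residual_rms`, `converged` and
#'   `n_starts_used`. Supports [tidy()], [glance()], [augment()] and
#'   [autoplot()].
#' @examples
#' solvents <- sesame_solvents()
#' truth <- c(17, 3, 5, 8)
#' red <- hansen_distance(truth[1], truth[2], truth[3],
#'                        solvents$delta_d, solvents$delta_p,
#'                        solvents$delta_h) / truth[4]
#' fit <- fit_hansen_sphere(dplyr::mutate(solvents, red = red))
#' glance(fit)
#' @export
fit_hansen_sphere <- function(data, n_starts = 16, bounds = hansen_fit_bounds(),
                              solute = NULL) {
  check_fit_input(data)
  lower <- bounds$lower
  upper <- bounds$upper
  starts <- halton_points(n_starts)
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ], lower = unname(lower), upper = unname(upper),
      fn = sphere_residuals, data = data,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    obj <- sum(sphere_residuals(fit$par, data)^2)
    if (is.null(best) || obj < best$objective) {
      best <- list(par = fit$par, objective = obj, info = fit$info)
    }
  }
  if (is.null(best)) {
    abort("All optimizer starts failed.", class = "solvscreen_fit_failure")
  }
  par <- setNames(as.numeric(best$par),
                  c("delta_d", "delta_p", "delta_h", "r_spher"))
  predicted <- hansen_distance(par[1], par[2], par[3],
                               data$delta_d, data$delta_p, data$delta_h) / par[4]
  residuals <- tibble::tibble(
    solvent = data$name,
    observed = data$red,
    predicted = predicted,
    residual = predicted - data$red
  )
  structure(list(
    sphere = tibble::tibble(name = solute %||% "solute",
                            delta_d = par[["delta_d"]], delta_p = par[["delta_p"]],
                            delta_h = par[["delta_h"]], r_spher = par[["r_spher"]]),
    par = par,
    objective = best$objective,
    residual_rms = sqrt(mean(residuals$residual^2)),
    residuals = residuals,
    converged = best$info %in% 1:3,
    n_starts_used = n_starts,
    bounds = bounds,
    data = tibble::as_tibble(data)
  ), class = "hansen_sphere_fit")
}

#' Grid-search reference fit for a Hansen sphere
#'
#' Exhaustive evaluation of the sphere-fitting objective on a regular grid
#' of centers over the parameter box, with the radius profiled out
#' analytically (for a fixed center the optimal `1/r_spher` is
#' `sum(d * red_obs) / sum(d^2)`, clamped to the radius bounds). Slow but
#' derivative-free: a reference against which the optimizer can be checked.
#'
#' @inheritParams fit_hansen_sphere
#' @param step Grid spacing for the three center coordinates, MPa^(1/2).
#' @return A list with elements `par` (named vector) and `objective`.
#' @export
grid_fit_sphere <- function(data, step = 0.25, bounds = hansen_fit_bounds()) {
  check_fit_input(data)
  lo <- bounds$lower
  hi <- bounds$upper
  grid <- expand.grid(
    delta_d = seq(lo[["delta_d"]], hi[["delta_d"]], by = step),
    delta_p = seq(lo[["delta_p"]], hi[["delta_p"]], by = step),
    delta_h = seq(lo[["delta_h"]], hi[["delta_h"]], by = step),
    KEEP.OUT.ATTRS = FALSE
  )
  obs <- data$red
  # distance matrix: grid centers x solvents
  d2 <- matrix(0, nrow(grid), nrow(data))
  for (j in seq_len(nrow(data))) {
    d2[, j] <- 4 * (grid$delta_d - data$delta_d[j])^2 +
      (grid$delta_p - data$delta_p[j])^2 +
      (grid$delta_h - data$delta_h[j])^2
  }
  d <- sqrt(d2)
  s_dd <- rowSums(d2)
  s_do <- as.numeric(d %*% obs)
  inv_r <- pmin(pmax(s_do / s_dd, 1 / hi[["r_spher"]]), 1 / lo[["r_spher"]])
  objective <- inv_r^2 * s_dd - 2 * inv_r * s_do + sum(obs^2)
  k <- which.min(objective)
  list(par = c(delta_d = grid$delta_d[k], delta_p = grid$delta_p[k],
               delta_h = grid$delta_h[k], r_spher = 1 / inv_r[k]),
       objective = objective[k])
}

#' Leave-one-out RED prediction
#'
#' Holds one solvent out, fits the Hansen sphere on the remaining solvents
#' and predicts the held-out solvent's RED from the fitted sphere: a
#' self-consistency check of an observed RED row.
#'
#' @inheritParams fit_hansen_sphere
#' @param held_out Name of the solvent to hold out (`data$name`).
#' @return The predicted RED for the held-out solvent (numeric scalar).
#' @export
loo_predict_red <- function(data, held_out, n_starts = 16,
                            bounds = hansen_fit_bounds()) {
  check_fit_input(data, min_solvents = 6)
  if (!held_out %in% data$name) {
    abort(sprintf("Unknown solvent `%s`.", held_out),
          class = "solvscreen_unknown_identifier")
  }
  rest <- data[data$name != held_out, , drop = FALSE]
  out <- data[data$name == held_out, , drop = FALSE]
  fit <- fit_hansen_sphere(rest, n_starts = n_starts, bounds = bounds)
  p <- fit$par
  as.numeric(hansen_distance(p[1], p[2], p[3],
                             out$delta_d, out$delta_p, out$delta_h) / p[4])
}

#' Fit Hansen spheres for every solute of a RED table
#'
#' @param solvents Data frame with `name`, `delta_d`, `delta_p`, `delta_h`.
#' @param red_table Long tibble with `solute`, `solvent`, `red` (as returned
#'   by [sesame_red_table()] or [read_red_matrix()]).
#' @param ... Passed on to [fit_hansen_sphere()].
#' @return A tibble with one row per solute: the fitted sphere parameters,
#'   `residual_rms`, `objective`, `converged`, and the full fit object in a
#'   `fit` list-column.
#' @export
fit_sphere_table <- function(solvents, red_table, ...) {
  check_hsp_frame(solvents, c("name", "delta_d", "delta_p", "delta_h"), "solvents")
  red_table |>
    dplyr::inner_join(solvents, by = c(solvent = "name")) |>
    dplyr::rename(name = "solvent") |>
    tidyr::nest(.by = "solute") |>
    dplyr::mutate(fit = purrr::map2(.data$data, .data$solute,
                                    \(d, s) fit_hansen_sphere(d, solute = s, ...))) |>
    dplyr::mutate(
      delta_d = purrr::map_dbl(.data$fit, \(f) f$par[["delta_d"]]),
      delta_p = purrr::map_dbl(.data$fit, \(f) f$par[["delta_p"]]),
      delta_h = purrr::map_dbl(.data$fit, \(f) f$par[["delta_h"]]),
      r_spher = purrr::map_dbl(.data$fit, \(f) f$par[["r_spher"]]),
      residual_rms = purrr::map_dbl(.data$fit, "residual_rms"),
      objective = purrr::map_dbl(.data$fit, "objective"),
      converged = purrr::map_lgl(.data$fit, "converged")
    ) |>
    dplyr::select("solute", "delta_d", "delta_p", "delta_h", "r_spher",
                  "residual_rms", "objective", "converged", "fit")
}

#' @export
print.hansen_sphere_fit <- function(x, ...) {
  cat("<hansen_sphere_fit>\n")
  cat(sprintf("  center: (%.3f, %.3f, %.3f) MPa^(1/2), r_spher = %.3f\n",
              x$par[1], x$par[2], x$par[3], x$par[4]))
  cat(sprintf("  %d solvents, objective %.3g, residual RMS %.3g, converged: %s\n",
              nrow(x$residuals), x$objective, x$residual_rms, x$converged))
  invisible(x)
}

#' @rdname fit_hansen_sphere
#' @param x,object A `hansen_sphere_fit`.
#' @param ... Unused.
#' @method tidy hansen_sphere_fit
#' @export
tidy.hansen_sphere_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = as.numeric(x$par))
}

#' @rdname fit_hansen_sphere
#' @method glance hansen_sphere_fit
#' @export
glance.hansen_sphere_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, residual_rms = x$residual_rms,
                 n_solvents = nrow(x$residuals), converged = x$converged,
                 n_starts_used = x$n_starts_used)
}

#' @rdname fit_hansen_sphere
#' @method augment hansen_sphere_fit
#' @export
augment.hansen_sphere_fit <- function(x, ...) {
  x$residuals
}

#' @rdname fit_hansen_sphere
#' @method autoplot hansen_sphere_fit
#' @export
autoplot.hansen_sphere_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$solvent), vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Observed RED", y = "Predicted RED",
                  title = "Hansen sphere fit: observed vs predicted RED")
}
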