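# Screening report: joins in-silico solvent scores (RED, relative
# solubility) with experimental endpoints (yield, composition totals,
# phenolics, antioxidant assays) and quantifies their agreement through
# Pearson correlations and Spearman rank concordance.

# direction metadata: +1 = larger is stronger/better, -1 = lower is stronger
# (IC50/EC50-type endpoints)
ENDPOINT_DIRECTIONS <- c(tpc = 1, tac = 1, dpph_ic50 = -1, frap_ec50 = -1)
DRIVER_COLUMNS <- c("sterol_total", "tocopherol_total", "tpc")

#' Pearson product-moment correlation with guards
#'
#' Thin wrapper around [stats::cor.test()] that enforces the preconditions
#' useful in small screening tables: equal lengths of at least 3 and
#' non-degenerate variance on both sides. P-values are descriptive
#' (unadjusted).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.", class = "solvscreen_shape_error")
  }
  if (length(x) < 3) {
    abort("Correlation needs at least 3 observations.",
          class = "solvscreen_insufficient_overlap")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance: correlation undefined.",
          class = "solvscreen_degenerate_input")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Spearman rank concordance between two solvent rankings
#'
#' Spearman's rho between two rankings of the same item set, aligned by
#' name, with average-rank tie handling.
#'
#' @param rank_a,rank_b Named numeric vectors (or rank vectors over the same
#'   names) covering an identical item set.
#' @return Spearman's rho in `[-1, 1]`.
#' @examples
#' spearman_concordance(c(a = 1, b = 2, c = 3), c(a = 1, b = 3, c = 2))
#' @export
spearman_concordance <- function(rank_a, rank_b) {
  if (is.null(names(rank_a)) || is.null(names(rank_b)) ||
      !setequal(names(rank_a), names(rank_b)) ||
      length(rank_a) != length(rank_b)) {
    abort("`rank_a` and `rank_b` must be named over the same item set.",
          class = "solvscreen_identifier_error")
  }
  b <- rank_b[names(rank_a)]
  as.numeric(cor(rank(rank_a), rank(b), method = "spearman"))
}

#' Build a joined in-silico vs experimental screening report
#'
#' Assembles one row per solvent from a RED screening grid, a ranked
#' relative-solubility table, fatty-acid class summaries and a bioactivity
#' table; then computes (a) Pearson correlations of each antioxidant
#' endpoint against the sterol, tocopherol and phenol totals -- with each
#' endpoint's direction metadata (lower-is-stronger for IC50/EC50) carried
#' explicitly rather than sign-flipped -- and (b) Spearman concordance
#' between the RED-based, relative-solubility-based and yield-based solvent
#' orderings. Solvents are joined by name (inner join; unmatched names are
#' recorded, not dropped silently).
#'
#' @param screen `red_screen` tibble from [screen_solvents()] (or any long
#'   tibble with `solute`, `solvent`, `red`).
#' @param rel_sol Ranked long tibble from [rank_relative_solubility()].
#' @param quality Class-summary tibble from [fatty_acid_class_sums()]
#'   (column `sample` holds the solvent name).
#' @param bioactivity Per-solvent endpoints: `solvent`, `tpc`, `tac`,
#'   `dpph_ic50`, `frap_ec50`, `extraction_yield`, plus joined totals
#'   `sterol_total`, `tocopherol_total` when available.
#' @param aggregate How to collapse per-solute RED values into one score
#'   per solvent: `"mean"` (default), `"median"` or `"worst"` (maximum).
#' @param reported Optional tibble of published correlation coefficients
#'   (`endpoint`, `driver`, `reported_r`) compared informationally; default
#'   [sesame_reported_correlations()] when the endpoints match, else none.
#' @return An object of class `screening_report` with elements `solvents`
#'   (the joined per-solvent table with in-silico scores and ranks),
#'   `correlations`, `concordance`, `aggregate` and `unmatched`. Supports
#'   [tidy()] (correlations), [glance()] (concordance) and [autoplot()].
#' @examples
#' screen <- sesame_red_screen()
#' rel <- rank_relative_solubility(sesame_relative_solubility())
#' quality <- fatty_acid_class_sums(sesame_fatty_acids())
#' bio <- sesame_bioactivity_joined()
#' report <- build_screening_report(screen, rel, quality, bio)
#' tidy(report)
#' @export
build_screening_report <- function(screen, rel_sol, quality, bioactivity,
                                   aggregate = c("mean", "median", "worst"),
                                   reported = NULL) {
  aggregate <- match.arg(aggregate)
  agg_fun <- switch(aggregate, mean = mean, median = stats::median, worst = max)

  red_scores <- screen |>
    dplyr::summarise(red_score = agg_fun(.data$red), .by = "solvent")
  rel_scores <- rel_sol |>
    dplyr::summarise(relsol_score = mean(.data$log10_x_rel), .by = "solvent")
  quality <- dplyr::rename(quality, solvent = "sample")

  all_names <- list(red_scores$solvent, rel_scores$solvent,
                    quality$solvent, bioactivity$solvent)
  shared <- Reduce(intersect, all_names)
  unmatched <- setdiff(Reduce(union, all_names), shared)
  if (length(shared) < 3) {
    abort(sprintf(
      "Only %d solvent(s) shared across inputs; need >= 3 to correlate.",
      length(shared)), class = "solvscreen_insufficient_overlap")
  }

  solvents <- red_scores |>
    dplyr::inner_join(rel_scores, by = "solvent") |>
    dplyr::inner_join(quality, by = "solvent") |>
    dplyr::inner_join(bioactivity, by = "solvent") |>
    dplyr::mutate(
      red_rank = dplyr::row_number(.data$red_score),           # low RED = good
      relsol_rank = dplyr::row_number(-.data$relsol_score),    # high log10 = good
      yield_rank = dplyr::row_number(-.data$extraction_yield)  # high yield = good
    )

  drivers <- intersect(DRIVER_COLUMNS, names(solvents))
  # TPC acts as a composition driver; the activity endpoints are correlated
  # against the three totals
  endpoints <- intersect(c("tac", "dpph_ic50", "frap_ec50"), names(solvents))
  correlations <- tidyr::expand_grid(endpoint = endpoints, driver = drivers) |>
    dplyr::filter(.data$endpoint != .data$driver) |>
    purrr::pmap(\(endpoint, driver) {
      stat <- pearson_correlation(solvents[[endpoint]], solvents[[driver]])
      tibble::tibble(endpoint = endpoint, driver = driver,
                     direction = unname(ENDPOINT_DIRECTIONS[endpoint]), stat)
    }) |>
    purrr::list_rbind()

  if (is.null(reported) && all(c("tac", "dpph_ic50", "frap_ec50") %in% endpoints)) {
    reported <- sesame_reported_correlations()
  }
  if (!is.null(reported)) {
    correlations <- correlations |>
      dplyr::left_join(reported, by = c("endpoint", "driver")) |>
      dplyr::mutate(abs_difference = abs(.data$r - .data$reported_r))
  }

  rank_of <- function(col) setNames(solvents[[col]], solvents$solvent)
  pairs <- tibble::tribble(
    ~comparison, ~a, ~b,
    "red_vs_relsol", "red_rank", "relsol_rank",
    "red_vs_yield", "red_rank", "yield_rank",
    "relsol_vs_yield", "relsol_rank", "yield_rank"
  )
  concordance <- pairs |>
    dplyr::mutate(
      rho = purrr::map2_dbl(.data$a, .data$b,
                            \(a, b) spearman_concordance(rank_of(a), rank_of(b))),
      n = nrow(solvents)
    ) |>
    dplyr::select("comparison", "rho", "n")

  structure(list(solvents = solvents, correlations = correlations,
                 concordance = concordance, aggregate = aggregate,
                 unmatched = unmatched),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d solvents (RED aggregated by %s)\n",
              nrow(x$solvents), x$aggregate))
  if (length(x$unmatched) > 0) {
    cat("  unmatched solvent names:", paste(x$unmatched, collapse = ", "), "\n")
  }
  cat("\nRank concordance (Spearman rho):\n")
  print(as.data.frame(x$concordance), row.names = FALSE)
  cat("\nComposition-activity correlations:\n")
  print(as.data.frame(x$correlations), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname build_screening_report
#' @param x,object A `screening_report`.
#' @param ... Unused.
#' @method tidy screening_report
#' @export
tidy.screening_report <- function(x, ...) {
  x$correlations
}

#' @rdname build_screening_report
#' @method glance screening_report
#' @export
glance.screening_report <- function(x, ...) {
  x$concordance |>
    tidyr::pivot_wider(names_from = "comparison", values_from = "rho",
                       names_prefix = "rho_") |>
    dplyr::mutate(n_solvents = nrow(x$solvents), aggregate = x$aggregate)
}

#' @rdname build_screening_report
#' @method autoplot screening_report
#' @export
autoplot.screening_report <- function(object, ...) {
  ggplot2::ggplot(object$correlations,
                  ggplot2::aes(.data$driver, .data$endpoint, fill = .data$r)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  name = "Pearson r") +
    ggplot2::labs(x = "Composition total", y = "Endpoint",
                  title = "Composition-activity correlations (descriptive)")
}
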