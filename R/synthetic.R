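# Synthetic-data generators: every input the screening pipeline consumes
# can be produced with known ground truth, so recovery and calibration are
# testable end-to-end without external data. All draws are seeded; a given
# spec reproduces bit-identical output.

#' Specification for synthetic screening inputs
#'
#' Defaults mirror the scale of a six-solvent seed-oil screening study:
#' 6 solvents with HSPs spanning the common extraction-solvent region,
#' a lipid-like solute sphere, 10 fatty acids covering all three saturation
#' classes, and bioactivity endpoints with a controlled linear correlation
#' to a composition driver.
#'
#' @param seed Integer seed fixing every downstream draw.
#' @param n_solvents Number of solvents to generate.
#' @param hsp_ranges List of `c(low, high)` ranges (MPa^(1/2)) for
#'   `delta_d`, `delta_p`, `delta_h`. The defaults bracket typical
#'   extraction solvents (hexane through ethanol).
#' @param sphere_truth Named vector `delta_d`, `delta_p`, `delta_h`,
#'   `r_spher`: the generating solute sphere.
#' @param red_noise_sd Gaussian noise sd added to generated RED values
#'   (truncated at 0; RED is non-negative by definition).
#' @param n_fatty_acids Number of fatty-acid codes in generated profiles.
#' @param composition_concentration Symmetric Dirichlet concentration for
#'   compositional draws (> 0; larger = closer to uniform shares).
#' @param target_correlation Population Pearson correlation between
#'   generated bioactivity endpoints and their driver, in `[-1, 1]`.
#' @param n_samples Number of samples (solvents) for composition and
#'   bioactivity tables.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1,
                       n_solvents = 6,
                       hsp_ranges = list(delta_d = c(13, 16),
                                         delta_p = c(0, 10),
                                         delta_h = c(0, 16)),
                       sphere_truth = c(delta_d = 17, delta_p = 3,
                                        delta_h = 5, r_spher = 8),
                       red_noise_sd = 0.05,
                       n_fatty_acids = 10,
                       composition_concentration = 1,
                       target_correlation = 0.9,
                       n_samples = 6) {
  if (red_noise_sd < 0) {
    abort("`red_noise_sd` must be >= 0.", class = "solvscreen_invalid_spec")
  }
  if (composition_concentration <= 0) {
    abort("`composition_concentration` must be > 0.",
          class = "solvscreen_invalid_spec")
  }
  if (abs(target_correlation) > 1) {
    abort("`target_correlation` must lie in [-1, 1].",
          class = "solvscreen_invalid_spec")
  }
  bad_range <- vapply(hsp_ranges, function(r) r[1] > r[2], logical(1))
  if (any(bad_range)) {
    abort(sprintf("Degenerate HSP range(s): %s.",
                  paste(names(hsp_ranges)[bad_range], collapse = ", ")),
          class = "solvscreen_invalid_spec")
  }
  structure(list(seed = seed, n_solvents = n_solvents,
                 hsp_ranges = hsp_ranges, sphere_truth = sphere_truth,
                 red_noise_sd = red_noise_sd, n_fatty_acids = n_fatty_acids,
                 composition_concentration = composition_concentration,
                 target_correlation = target_correlation,
                 n_samples = n_samples),
            class = "synth_spec")
}

with_gen_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Generate a synthetic solvent set
#'
#' HSPs drawn uniformly within the spec's per-component ranges; names are
#' deterministic (`"S1"`, `"S2"`, ...).
#'
#' @param spec A [synth_spec()].
#' @param seed Seed for this draw; default the spec's seed. `NULL` uses the
#'   ambient RNG state.
#' @return Tibble `name`, `delta_d`, `delta_p`, `delta_h`.
#' @export
gen_solvent_set <- function(spec, seed = spec$seed) {
  n <- spec$n_solvents
  if (n == 0) {
    return(tibble::tibble(name = character(), delta_d = numeric(),
                          delta_p = numeric(), delta_h = numeric()))
  }
  with_gen_seed(seed, {
    tibble::tibble(
      name = paste0("S", seq_len(n)),
      delta_d = runif(n, spec$hsp_ranges$delta_d[1], spec$hsp_ranges$delta_d[2]),
      delta_p = runif(n, spec$hsp_ranges$delta_p[1], spec$hsp_ranges$delta_p[2]),
      delta_h = runif(n, spec$hsp_ranges$delta_h[1], spec$hsp_ranges$delta_h[2])
    )
  })
}

#' Generate an observed RED row from a known sphere
#'
#' Forward model plus truncated Gaussian noise:
#' `RED_j = hansen_distance(center, solvent_j) / r_spher + eps_j`,
#' `eps_j ~ N(0, red_noise_sd)`, truncated at 0. The generating truth is
#' attached for downstream recovery scoring.
#'
#' @inheritParams gen_solvent_set
#' @param solvents Solvent tibble (`name`, `delta_d`, `delta_p`, `delta_h`).
#' @return Tibble `name`, `delta_d`, `delta_p`, `delta_h`, `red_true`,
#'   `red` (noisy, >= 0), with the generating sphere in attribute `truth`.
#' @export
gen_red_table <- function(spec, solvents, seed = spec$seed) {
  tr <- spec$sphere_truth
  red_true <- hansen_distance(tr[["delta_d"]], tr[["delta_p"]], tr[["delta_h"]],
                              solvents$delta_d, solvents$delta_p,
                              solvents$delta_h) / tr[["r_spher"]]
  red <- with_gen_seed(seed, {
    pmax(red_true + rnorm(length(red_true), 0, spec$red_noise_sd), 0)
  })
  out <- dplyr::mutate(tibble::as_tibble(solvents),
                       red_true = red_true, red = red)
  attr(out, "truth") <- tr
  out
}

default_fa_codes <- function(n) {
  if (n == 10) {
    # the classic seed-oil panel: spans all three classes
    return(c("C8:0", "C14:0", "C16:0", "C16:1", "C18:0",
             "C18:1", "C18:2", "C18:3", "C20:0", "C20:1"))
  }
  i <- seq_len(n) - 1
  sprintf("C%d:%d", 8 + 2 * (i %/% 3), i %% 3)
}

#' Generate compositional fatty-acid profiles
#'
#' Per sample, percentages are a symmetric Dirichlet draw (gamma shares
#' normalized to 100), so each sample closes exactly on 100 and the
#' SFA + MUFA + PUFA partition property holds by construction. Codes span
#' all three saturation classes.
#'
#' @inheritParams gen_solvent_set
#' @return Long tibble `sample`, `fatty_acid`, `percent`.
#' @export
gen_composition <- function(spec, seed = spec$seed) {
  if (spec$n_fatty_acids < 2) {
    abort("`n_fatty_acids` must be >= 2.", class = "solvscreen_invalid_spec")
  }
  codes <- default_fa_codes(spec$n_fatty_acids)
  with_gen_seed(seed, {
    purrr::map(seq_len(spec$n_samples), function(i) {
      g <- rgamma(spec$n_fatty_acids, shape = spec$composition_concentration)
      tibble::tibble(sample = paste0("S", i), fatty_acid = codes,
                     percent = 100 * g / sum(g))
    }) |>
      purrr::list_rbind()
  })
}

#' Generate bioactivity endpoints with a controlled correlation
#'
#' Each endpoint is `location + scale * (rho * z + sqrt(1 - rho^2) * eps)`
#' where `z` is the standardized driver and `eps` standard Gaussian noise,
#' so the population correlation with the driver equals the target.
#' IC50/EC50-type endpoints (lower = stronger activity) take the negative
#' target sign, mirroring their direction metadata.
#'
#' @inheritParams gen_solvent_set
#' @param driver Numeric vector of length `n_samples` (e.g. a sterol total
#'   per sample) the endpoints should correlate with.
#' @return Tibble `solvent`, `tpc`, `tac`, `dpph_ic50`, `frap_ec50` with
#'   the generating parameters in attribute `truth`.
#' @export
gen_bioactivity <- function(spec, driver, seed = spec$seed) {
  if (length(driver) != spec$n_samples) {
    abort("`driver` must have length `n_samples`.",
          class = "solvscreen_invalid_spec")
  }
  rho <- spec$target_correlation
  if (sd(driver) == 0) {
    abort("`driver` must have non-zero variance.",
          class = "solvscreen_degenerate_input")
  }
  z <- as.numeric(scale(driver))
  # magnitudes on the order of published seed-oil endpoint tables
  scales <- tibble::tribble(
    ~endpoint, ~location, ~scale,
    "tpc", 18, 6,
    "tac", 2.2, 1.2,
    "dpph_ic50", 110, 50,
    "frap_ec50", 730, 200
  )
  with_gen_seed(seed, {
    cols <- purrr::pmap(scales, function(endpoint, location, scale) {
      s <- unname(ENDPOINT_DIRECTIONS[endpoint]) * rho
      y <- s * z + sqrt(1 - rho^2) * rnorm(length(z))
      pmax(location + scale * y, 0)
    })
    names(cols) <- scales$endpoint
    out <- tibble::tibble(solvent = paste0("S", seq_len(spec$n_samples)),
                          !!!cols)
    attr(out, "truth") <- list(target_correlation = rho,
                               directions = ENDPOINT_DIRECTIONS[scales$endpoint])
    out
  })
}

#' Write a complete synthetic fixture directory
#'
#' Generates and writes every input the pipeline consumes: `solvents.csv`,
#' `red.csv` (observed RED with truth column), `relsol.csv` (normalized
#' relative solubility derived from the noise-free RED), `composition.csv`,
#' `bioactivity.csv` and `truth.json`.
#'
#' @inheritParams gen_solvent_set
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_fixtures <- function(spec, dir, seed = spec$seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  solvents <- gen_solvent_set(spec, seed = seed)
  red <- gen_red_table(spec, solvents, seed = seed + 1)
  composition <- gen_composition(spec, seed = seed + 2)
  sterol_driver <- with_gen_seed(seed + 3, runif(spec$n_samples, 400, 800))
  bio <- gen_bioactivity(spec, sterol_driver, seed = seed + 4)
  bio$sterol_total <- sterol_driver
  # a relative-solubility surrogate: less soluble the further from the
  # sphere (negative scaled noise-free RED), best solvent normalized to 0
  relsol <- tibble::tibble(
    solute = "synthetic-solute",
    solvent = red$name,
    log10_x = -red$red_true
  ) |>
    dplyr::mutate(log10_x_rel = normalize_best_to_zero(.data$log10_x))

  paths <- file.path(dir, c("solvents.csv", "red.csv", "relsol.csv",
                            "composition.csv", "bioactivity.csv", "truth.json"))
  readr::write_csv(solvents, paths[1])
  readr::write_csv(dplyr::select(red, "name", "red_true", "red"), paths[2])
  readr::write_csv(relsol, paths[3])
  readr::write_csv(composition, paths[4])
  readr::write_csv(bio, paths[5])
  jsonlite::write_json(
    list(seed = seed, sphere_truth = as.list(spec$sphere_truth),
         red_noise_sd = spec$red_noise_sd,
         target_correlation = spec$target_correlation),
    paths[6], auto_unbox = TRUE, digits = 12)
  invisible(paths)
}
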