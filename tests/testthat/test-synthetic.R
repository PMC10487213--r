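test_that("solvent generation is seeded, bounded and validates its spec", {
  spec <- synth_spec(seed = 5)
  expect_equal(nrow(gen_solvent_set(synth_spec(seed = 5, n_solvents = 0))), 0)
  a <- gen_solvent_set(spec)
  b <- gen_solvent_set(spec)
  expect_identical(a, b)
  expect_true(all(a$delta_d >= 13 & a$delta_d <= 16))
  expect_true(all(a$delta_p >= 0 & a$delta_p <= 10))
  expect_true(all(a$delta_h >= 0 & a$delta_h <= 16))
  # the default ranges bracket the packaged reference solvents
  ref <- sesame_solvents()
  expect_true(all(ref$delta_d >= 13 & ref$delta_d <= 16))
  expect_true(all(ref$delta_p >= 0 & ref$delta_p <= 10))
  expect_true(all(ref$delta_h >= 0 & ref$delta_h <= 16))
  expect_error(synth_spec(hsp_ranges = list(delta_d = c(16, 13),
                                            delta_p = c(0, 10),
                                            delta_h = c(0, 16))),
               class = "solvscreen_invalid_spec")
  expect_error(synth_spec(red_noise_sd = -0.1), class = "solvscreen_invalid_spec")
  expect_error(synth_spec(composition_concentration = 0),
               class = "solvscreen_invalid_spec")
  expect_error(synth_spec(target_correlation = 1.2),
               class = "solvscreen_invalid_spec")
})

test_that("RED generation follows the forward model with truncated noise", {
  spec0 <- synth_spec(seed = 8, red_noise_sd = 0)
  solvents <- gen_solvent_set(spec0)
  red0 <- gen_red_table(spec0, solvents)
  # noise-free values equal an independent evaluation of the forward model
  tr <- spec0$sphere_truth
  manual <- sqrt(4 * (tr[["delta_d"]] - solvents$delta_d)^2 +
                   (tr[["delta_p"]] - solvents$delta_p)^2 +
                   (tr[["delta_h"]] - solvents$delta_h)^2) / tr[["r_spher"]]
  expect_equal(red0$red, manual, tolerance = 1e-12)
  expect_equal(red0$red, red0$red_true)
  expect_equal(attr(red0, "truth"), tr)

  # a sphere centered exactly on a solvent gives a zero noise-free cell
  on_solvent <- synth_spec(seed = 8, red_noise_sd = 0,
                           sphere_truth = c(delta_d = solvents$delta_d[1],
                                            delta_p = solvents$delta_p[1],
                                            delta_h = solvents$delta_h[1],
                                            r_spher = 8))
  expect_equal(gen_red_table(on_solvent, solvents)$red[1], 0)

  # empirical noise sd per cell is close to the nominal sd
  spec <- synth_spec(seed = 8, red_noise_sd = 0.05)
  reps <- sapply(1:100, function(i) gen_red_table(spec, solvents, seed = 1000 + i)$red)
  cell_sd <- apply(reps, 1, sd)
  expect_true(all(cell_sd > 0.03 & cell_sd < 0.07))
  expect_true(all(reps >= 0))
})

test_that("compositional draws close exactly on 100 and flatten as concentration grows", {
  spec <- synth_spec(seed = 13)
  comp <- gen_composition(spec)
  totals <- dplyr::summarise(comp, total = sum(percent), .by = sample)
  expect_equal(totals$total, rep(100, spec$n_samples), tolerance = 1e-9)
  expect_identical(comp, gen_composition(spec))
  # all three saturation classes are represented
  expect_setequal(as.character(unique(classify_fatty_acid(comp$fatty_acid))),
                  c("SFA", "MUFA", "PUFA"))
  # large concentration concentrates shares near 100 / n
  flat <- gen_composition(synth_spec(seed = 13,
                                     composition_concentration = 5000))
  expect_true(all(abs(flat$percent - 10) < 2))
  expect_error(gen_composition(synth_spec(n_fatty_acids = 1)),
               class = "solvscreen_invalid_spec")
})

test_that("bioactivity generation hits its target correlation in the limiting cases", {
  driver <- c(400, 450, 520, 610, 700, 780)
  exact <- gen_bioactivity(synth_spec(seed = 17, target_correlation = 1), driver)
  expect_equal(cor(exact$tac, driver), 1, tolerance = 1e-12)
  # lower-is-stronger endpoints take the opposite sign
  expect_equal(cor(exact$dpph_ic50, driver), -1, tolerance = 1e-12)
  expect_identical(exact,
                   gen_bioactivity(synth_spec(seed = 17, target_correlation = 1),
                                   driver))

  null_spec <- synth_spec(target_correlation = 0, n_samples = 50)
  withr::with_seed(23, {
    rs <- vapply(1:200, function(i) {
      d <- rnorm(50)
      cor(gen_bioactivity(null_spec, d, seed = NULL)$tac, d)
    }, numeric(1))
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(gen_bioactivity(synth_spec(), driver = 1:3),
               class = "solvscreen_invalid_spec")
})

test_that("synthetic fixture directories round-trip through the package readers", {
  dir <- withr::local_tempdir()
  spec <- synth_spec(seed = 29)
  paths <- write_synthetic_fixtures(spec, dir)
  expect_true(all(file.exists(paths)))

  solvents <- read_solvent_set(file.path(dir, "solvents.csv"))
  expect_equal(solvents, gen_solvent_set(spec), tolerance = 1e-12)

  comp <- read_composition(file.path(dir, "composition.csv"), layout = "long")
  expect_equal(comp$percent, gen_composition(spec, seed = spec$seed + 2)$percent,
               tolerance = 1e-12)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$sphere_truth$r_spher, spec$sphere_truth[["r_spher"]])

  relsol <- readr::read_csv(file.path(dir, "relsol.csv"),
                            show_col_types = FALSE)
  expect_equal(max(relsol$log10_x_rel), 0)
})
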