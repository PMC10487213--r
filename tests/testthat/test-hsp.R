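test_that("total solubility parameter matches hand-evaluated reference values", {
  expect_identical(hsp_total(0, 0, 0), 0)
  # hand evaluation on the n-hexane and ethanol HSP triples
  expect_equal(hsp_total(13.9, 0.1, 0.1), 13.9007194058, tolerance = 1e-10)
  expect_equal(hsp_total(14, 9.1, 15.2), 22.5798582812, tolerance = 1e-10)
  # never below the largest component
  for (i in 1:20) {
    trip <- runif(3, 0, 20)
    expect_gte(hsp_total(trip[1], trip[2], trip[3]), max(trip))
  }
  expect_error(hsp_total(-1, 0, 0), class = "solvscreen_invalid_input")
  expect_error(hsp_total(NaN, 0, 0), class = "solvscreen_invalid_input")
})

test_that("hansen distance carries the factor-4 dispersion weight and is a scaled metric", {
  expect_identical(hansen_distance(15, 4, 3, 15, 4, 3), 0)
  # unit offset on the dispersion axis alone costs sqrt(4) = 2
  expect_equal(hansen_distance(15, 4, 3, 14, 4, 3), 2)
  # n-hexane vs MeTHF, hand-evaluated
  expect_equal(hansen_distance(13.9, 0.1, 0.1, 15, 4.7, 3.9),
               6.35924523823, tolerance = 1e-10)
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- runif(3, 0, 20)
      b <- runif(3, 0, 20)
      d <- hansen_distance(a[1], a[2], a[3], b[1], b[2], b[3])
      expect_gte(d, 0)
      # symmetry
      expect_equal(d, hansen_distance(b[1], b[2], b[3], a[1], a[2], a[3]))
      # homogeneity: scaling all six coordinates by c scales the distance by c
      c_ <- runif(1, 0.1, 5)
      expect_equal(hansen_distance(c_ * a[1], c_ * a[2], c_ * a[3],
                                   c_ * b[1], c_ * b[2], c_ * b[3]),
                   c_ * d, tolerance = 1e-12)
    }
  })
  expect_error(hansen_distance(Inf, 0, 0, 1, 1, 1),
               class = "solvscreen_invalid_input")
})

test_that("RED numbers divide distance by radius and classify on the strict unit boundary", {
  expect_identical(red_number(0, 5), 0)
  expect_equal(red_number(3.3, 3.3), 1)
  expect_equal(red_number(6, 4), 1.5)
  # scale invariance of the ratio
  expect_equal(red_number(6 * 2.7, 4 * 2.7), 1.5)
  expect_error(red_number(1, 0), class = "solvscreen_invalid_sphere")
  expect_error(red_number(-1, 1), class = "solvscreen_invalid_input")

  expect_equal(as.character(classify_red(c(0.31, 2.94, 1, 0.999999))),
               c("suitable", "unsuitable", "unsuitable", "suitable"))
  expect_error(classify_red(-0.1), class = "solvscreen_invalid_input")
})

test_that("screen_solvents matches the nested-loop oracle and ranks each solute row", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      solvents <- random_solvents(6)
      solutes <- tibble::tibble(
        name = paste0("U", 1:3),
        delta_d = runif(3, 13, 20), delta_p = runif(3, 0, 12),
        delta_h = runif(3, 0, 18), r_spher = runif(3, 2, 12)
      )
      screen <- screen_solvents(solvents, solutes)
      oracle <- oracle_red_matrix(solutes, solvents)
      wide <- red_matrix(screen)
      expect_equal(unname(as.matrix(wide[, -1])), unname(oracle),
                   tolerance = 1e-12)
      # ranks are a permutation of 1..n within each solute
      ranks <- split(screen$rank, screen$solute)
      for (r in ranks) expect_setequal(r, seq_along(r))
      # rank 1 attains the row minimum RED
      best <- dplyr::filter(screen, rank == 1)
      mins <- dplyr::summarise(screen, m = min(red), .by = solute)
      expect_equal(dplyr::arrange(best, solute)$red,
                   dplyr::arrange(mins, solute)$m)
    }
  })
})

test_that("screening is deterministic: duplicated solutes give identical rows, ties follow input order", {
  solvents <- sesame_solvents()
  sphere <- tibble::tibble(name = c("A", "B"), delta_d = 16, delta_p = 4,
                           delta_h = 4, r_spher = 7)
  screen <- screen_solvents(solvents, sphere)
  a <- dplyr::filter(screen, solute == "A")
  b <- dplyr::filter(screen, solute == "B")
  expect_equal(a$red, b$red)
  expect_equal(a$rank, b$rank)

  # two solvents equidistant from the center: first in input order wins rank 1
  tied <- tibble::tibble(name = c("V1", "V2"),
                         delta_d = c(15, 17), delta_p = 4, delta_h = 4)
  center <- tibble::tibble(name = "U", delta_d = 16, delta_p = 4,
                           delta_h = 4, r_spher = 5)
  s <- screen_solvents(tied, center)
  expect_equal(s$red[1], s$red[2])
  expect_equal(s$rank, c(1L, 2L))
})

test_that("screening validates its inputs", {
  solvents <- sesame_solvents()
  sphere <- tibble::tibble(name = "U", delta_d = 16, delta_p = 4,
                           delta_h = 4, r_spher = 7)
  expect_error(screen_solvents(solvents[0, ], sphere),
               class = "solvscreen_empty_input")
  expect_error(screen_solvents(dplyr::bind_rows(solvents, solvents[1, ]), sphere),
               class = "solvscreen_duplicate_identifier")
  expect_error(
    screen_solvents(solvents, dplyr::mutate(sphere, r_spher = 0)),
    class = "solvscreen_invalid_sphere")
})

test_that("an observed RED table is classified and ranked like a screening result", {
  screen <- as_red_screen(sesame_red_table())
  expect_s3_class(screen, "red_screen")
  expect_equal(nrow(screen), 30)
  ranks <- split(screen$rank, screen$solute)
  for (r in ranks) expect_setequal(r, 1:6)
  # d-limonene has the lowest printed RED for the tocopherol and sterol rows
  best_toc <- dplyr::filter(screen, solute == "gamma-Tocopherol", rank == 1)
  expect_equal(best_toc$solvent, "d-Limonene")
})
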