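test_that("pearson correlation matches hand evaluation and guards degeneracy", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  # hand-evaluated product-moment coefficient
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$n, 4)
  expect_error(pearson_correlation(1:4, rep(2, 4)),
               class = "solvscreen_degenerate_input")
  expect_error(pearson_correlation(1:4, 1:5), class = "solvscreen_shape_error")
  expect_error(pearson_correlation(1:2, 2:1),
               class = "solvscreen_insufficient_overlap")
})

test_that("spearman concordance scores ranking agreement with average-rank ties", {
  nm <- paste0("s", 1:6)
  r1 <- setNames(1:6, nm)
  expect_equal(spearman_concordance(r1, r1), 1)
  expect_equal(spearman_concordance(r1, setNames(6:1, nm)), -1)
  # one adjacent swap at n = 6: rho = 1 - 6*2/(6*35)
  expect_equal(spearman_concordance(r1, setNames(c(2, 1, 3, 4, 5, 6), nm)),
               0.942857142857, tolerance = 1e-10)
  # invariant under monotone relabeling of the scores
  expect_equal(spearman_concordance(setNames(exp(1:6), nm), r1), 1)
  expect_error(spearman_concordance(r1, setNames(1:6, paste0("x", 1:6))),
               class = "solvscreen_identifier_error")
})

sesame_report <- function(aggregate = "mean") {
  build_screening_report(
    screen = sesame_red_screen(),
    rel_sol = rank_relative_solubility(sesame_relative_solubility()),
    quality = fatty_acid_class_sums(sesame_fatty_acids()),
    bioactivity = sesame_bioactivity_joined(),
    aggregate = aggregate
  )
}

test_that("the sesame screening report joins six solvents with populated statistics", {
  report <- sesame_report()
  expect_s3_class(report, "screening_report")
  expect_equal(nrow(report$solvents), 6)
  expect_equal(report$unmatched, character(0))
  expect_true(all(abs(report$correlations$r) <= 1))
  expect_true(all(report$correlations$n == 6))
  expect_true(all(abs(report$concordance$rho) <= 1))
  expect_equal(nrow(report$correlations), 9) # 3 activity endpoints x 3 composition drivers
  # published coefficients are compared informationally, never asserted equal
  expect_true(all(c("reported_r", "abs_difference") %in% names(report$correlations)))
  expect_true(all(is.finite(report$correlations$abs_difference)))
  # direction metadata rides along instead of silently flipping signs
  expect_equal(unique(report$correlations$direction[
    report$correlations$endpoint == "dpph_ic50"]), -1)
  g <- glance(report)
  expect_true(all(c("rho_red_vs_yield", "n_solvents") %in% names(g)))
})

test_that("the report is insensitive to input row order and validates overlap", {
  report <- sesame_report()
  withr::with_seed(73, {
    shuf <- function(d) d[sample(nrow(d)), ]
    report2 <- build_screening_report(
      screen = shuf(sesame_red_screen()),
      rel_sol = shuf(rank_relative_solubility(sesame_relative_solubility())),
      quality = shuf(fatty_acid_class_sums(sesame_fatty_acids())),
      bioactivity = shuf(sesame_bioactivity_joined())
    )
  })
  expect_equal(dplyr::arrange(report2$correlations, endpoint, driver),
               dplyr::arrange(report$correlations, endpoint, driver))
  expect_equal(report2$concordance, report$concordance)

  disjoint <- dplyr::mutate(sesame_bioactivity_joined(),
                            solvent = paste0("other_", solvent))
  expect_error(
    build_screening_report(sesame_red_screen(),
                           rank_relative_solubility(sesame_relative_solubility()),
                           fatty_acid_class_sums(sesame_fatty_acids()),
                           disjoint),
    class = "solvscreen_insufficient_overlap")
})

test_that("RED aggregation mode changes the in-silico ranking input, not the join", {
  for (mode in c("mean", "median", "worst")) {
    rep <- sesame_report(aggregate = mode)
    expect_equal(nrow(rep$solvents), 6)
    expect_setequal(rep$solvents$red_rank, 1:6)
  }
})

test_that("small-n correlation estimates bracket a known generating correlation", {
  # calibration at the study scale (n = 6): the sampling distribution of r
  # is wide but must bracket the generating value
  spec <- synth_spec(target_correlation = 0.9, n_samples = 6)
  withr::with_seed(91, {
    rs <- vapply(1:300, function(i) {
      driver <- runif(6, 400, 800)
      bio <- gen_bioactivity(spec, driver, seed = NULL)
      cor(bio$tac, driver)
    }, numeric(1))
  })
  qs <- unname(stats::quantile(rs, c(0.05, 0.95)))
  expect_lt(qs[1], 0.9)
  expect_gt(qs[2], 0.9)
  expect_gt(mean(rs), 0.6)
})
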