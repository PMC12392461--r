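make_points <- function(top, ec50, hill = 1, n = 12, dilution = 2,
                        cmax = 50 * ec50) {
  conc <- cmax / dilution^(seq_len(n) - 1)
  tibble::tibble(concentration = conc,
                 response = top / (1 + (ec50 / conc)^hill))
}

test_that("cytotoxicity masking keeps concentrations strictly below IC10", {
  pts <- tibble::tibble(concentration = c(1e-7, 1e-6, 1e-5),
                        response = c(1, 5, 20))
  expect_equal(mask_cytotoxic(pts, 5e-6)$concentration, c(1e-7, 1e-6))
  expect_equal(mask_cytotoxic(pts, NA), pts)           # censored: no masking
  expect_equal(nrow(mask_cytotoxic(pts, 1e-8)), 0L)    # all removed
  # boundary is strict
  expect_equal(mask_cytotoxic(pts, 1e-6)$concentration, 1e-7)
  expect_error(mask_cytotoxic(pts, -1), "> 0")
})

test_that("noise-free log-logistic data are recovered exactly", {
  f <- fit_curve(make_points(38, 1e-6, 1))
  expect_equal(f$top, 38, tolerance = 1e-3)
  expect_equal(f$ec50, 1e-6, tolerance = 1e-3)
  expect_equal(f$hill, 1, tolerance = 1e-3)
  bm <- benchmark_concentration(f, "EC10")
  expect_equal(bm$benchmark, 1e-6 / (38 / 10 - 1), tolerance = 1e-3)
  expect_false(bm$censored)
  expect_true(bm$active)
})

test_that("few distinct concentrations raise an error", {
  pts <- make_points(50, 1e-6)[1:3, ]
  expect_error(fit_curve(pts), "4 distinct")
})

test_that("inversion consistency holds across tops and Hill slopes", {
  for (top in c(12, 25, 50, 80, 100)) {
    for (hill in c(0.5, 1, 2)) {
      ec50 <- 10^stats::runif(1, -7, -5)
      f <- fit_curve(make_points(top, ec50, hill, cmax = 500 * ec50))
      bm <- benchmark_concentration(f, "EC10")
      truth <- ec50 / (top / 10 - 1)^(1 / hill)
      expect_equal(bm$benchmark, truth, tolerance = 1e-3)
      # benchmark lies below the EC50 for clearly supra-threshold tops
      if (top > 20) expect_lt(bm$benchmark, f$ec50)
    }
  }
})

test_that("EC10 increases with ec50 at fixed top", {
  ec50s <- c(1e-7, 1e-6, 1e-5)
  bms <- vapply(ec50s, function(e) {
    benchmark_concentration(fit_curve(make_points(40, e)))$benchmark
  }, numeric(1))
  expect_true(all(diff(bms) > 0))
})

test_that("EC10 is invariant to points above the masking threshold", {
  pts <- make_points(38, 1e-6)
  ic10 <- 3e-5
  masked <- mask_cytotoxic(pts, ic10)
  extra <- tibble::tibble(concentration = c(5e-5, 1e-4),
                          response = c(90, 120))  # cytotoxic artifacts
  bm1 <- benchmark_concentration(fit_curve(masked))
  bm2 <- benchmark_concentration(
    fit_curve(mask_cytotoxic(dplyr::bind_rows(pts, extra), ic10)))
  expect_equal(bm1$benchmark, bm2$benchmark)
})

test_that("sub-threshold efficacy is censored, not an error", {
  f <- fit_curve(make_points(8, 1e-6))
  bm <- benchmark_concentration(f, "EC10")
  expect_true(bm$censored)
  expect_false(bm$active)
  expect_true(is.na(bm$benchmark))
})

test_that("benchmarks beyond the tested range are right-censored", {
  # top barely above threshold: inversion lands far above cmax
  pts <- make_points(10.5, 1e-6, cmax = 2e-6)
  bm <- benchmark_concentration(fit_curve(pts), "EC10")
  expect_true(bm$censored)
  expect_equal(bm$cmax, 2e-6)
})

test_that("cytotoxicity fitted on the inhibition scale gives an IC10", {
  # monotone-decreasing viability converted to inhibition, full curve
  pts <- make_points(100, 1e-5, 1.5)
  f <- fit_curve(pts)
  expect_equal(f$top, 100, tolerance = 1e-3)
  bm <- benchmark_concentration(f, "IC10")
  expect_equal(bm$benchmark, 1e-5 / (100 / 10 - 1)^(1 / 1.5),
               tolerance = 1e-3)
})

test_that("noisy replicate curves recover the top within +/-5 points", {
  spec <- generator_spec(true_top = 66, true_ec50 = 8e-6, true_hill = 1,
                         noise_sd = 5, n_replicates = 3, seed = 42)
  f <- fit_curve(simulate_concentration_response(spec))
  expect_lt(abs(emax_percent(f) - 66), 5)
  expect_equal(f$model, "log_logistic")
})

test_that("induction-ratio curves are evaluated at IR = 1.5", {
  # linear IR data: IR = 1 + 2.5e5 * c crosses 1.5 at 2e-6 exactly
  conc <- 10^seq(-7, -5.2, length.out = 8)
  pts <- tibble::tibble(concentration = conc, response = 2.5e5 * conc)
  f <- fit_curve(pts, model = "linear_low_effect")
  bm <- benchmark_concentration(f, "EC_IR1.5")
  expect_equal(bm$benchmark, 2e-6, tolerance = 1e-9)
  # no induction -> censored
  flat <- tibble::tibble(concentration = conc, response = rep(0, 8))
  expect_true(benchmark_concentration(
    fit_curve(flat, model = "linear_low_effect"), "EC_IR1.5")$censored)
})

test_that("emax_percent returns the fitted top on the reference scale", {
  expect_equal(emax_percent(fit_curve(make_points(80, 1e-6))), 80,
               tolerance = 1e-3)
  spec <- generator_spec(true_top = 66, true_ec50 = 1e-6, noise_sd = 5,
                         seed = 7)
  expect_lt(abs(emax_percent(fit_curve(
    simulate_concentration_response(spec))) - 66), 5)
})

test_that("median IC10 excludes censored values and reports the count", {
  expect_equal(median_ic10(c(1e-5, 2e-5, 3e-5)), 2e-5)
  expect_equal(median_ic10(1e-5), 1e-5)
  expect_message(m <- median_ic10(c(1e-5, 2e-5, NA)), "1 censored")
  expect_equal(m, 1.5e-5)
  expect_true(is.na(suppressMessages(median_ic10(c(NA_real_, NA_real_)))))
})

test_that("benchmark strings round-trip including censoring markers", {
  s <- format_benchmark(c(3.7e-7, NA), cmax = c(NA, 1.8e-2))
  expect_equal(s[2], ">0.018")
  back <- parse_benchmark(s)
  expect_equal(back$value, c(3.7e-7, NA))
  expect_equal(back$censored, c(FALSE, TRUE))
  expect_equal(back$cmax[2], 0.018)
})

test_that("fit_assay_table fits each compound-assay pair once with masking", {
  spec_a <- generator_spec(true_top = 40, true_ec50 = 1e-6, noise_sd = 0,
                           compound_id = "X", assay_id = "ERalpha")
  spec_b <- generator_spec(true_top = 8, true_ec50 = 1e-6, noise_sd = 0,
                           compound_id = "Y", assay_id = "ERalpha")
  resp <- dplyr::bind_rows(simulate_concentration_response(spec_a),
                           simulate_concentration_response(spec_b))
  out <- fit_assay_table(resp,
                         ic10_lookup = tibble::tibble(compound_id = c("X", "Y"),
                                                      ic10 = c(NA, NA)))
  expect_equal(nrow(out), 2L)
  expect_false(out$censored[out$compound_id == "X"])
  expect_true(out$censored[out$compound_id == "Y"])
  expect_equal(out$emax[out$compound_id == "X"], 40, tolerance = 1e-3)
})
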