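test_that("noise-free simulation lies exactly on the generating curve", {
  spec <- generator_spec(true_top = 38, true_ec50 = 1e-6, true_hill = 1,
                         noise_sd = 0)
  pts <- simulate_concentration_response(spec)
  expect_equal(nrow(pts), 12 * 3)
  mu <- 38 / (1 + (1e-6 / pts$concentration))
  expect_equal(pts$response, mu)
  # geometric series with the requested dilution factor
  conc <- sort(unique(pts$concentration))
  expect_equal(conc[-1] / conc[-length(conc)], rep(2, 11))
})

test_that("a fixed seed reproduces the dataset bit-identically", {
  spec <- generator_spec(true_top = 50, true_ec50 = 1e-6, noise_sd = 5,
                         seed = 99)
  expect_identical(simulate_concentration_response(spec),
                   simulate_concentration_response(spec))
  spec2 <- generator_spec(true_top = 50, true_ec50 = 1e-6, noise_sd = 5,
                          seed = 100)
  expect_false(identical(simulate_concentration_response(spec)$response,
                         simulate_concentration_response(spec2)$response))
})

test_that("physical truncation applies per response scale", {
  spec <- generator_spec(true_top = 20, true_ec50 = 1e-6, noise_sd = 30,
                         response_scale = "percent_inhibition", seed = 5)
  y <- simulate_concentration_response(spec)$response
  expect_true(all(y >= 0 & y <= 100))
  spec_ir <- generator_spec(true_top = 2, true_ec50 = 1e-6, noise_sd = 3,
                            response_scale = "induction_ratio", seed = 5)
  expect_true(all(simulate_concentration_response(spec_ir)$response >= 0))
})

test_that("EC10 recovery is unbiased and at the design's precision limit", {
  # Under the default design (12 two-fold dilutions, 3 replicates, additive
  # noise SD 5 on the % scale) the Cramer-Rao bound for the inverted EC10 is
  # ~0.16 relative SE even for a favorable curve (top 80, hill 1); the fit
  # should be unbiased and not lose efficiency against that floor.
  set.seed(1234)
  errs <- replicate(50, {
    top <- stats::runif(1, 15, 100)
    ec50 <- 10^stats::runif(1, -7, -5)
    hill <- stats::runif(1, 0.7, 2)
    spec <- generator_spec(true_top = top, true_ec50 = ec50,
                           true_hill = hill, noise_sd = 5,
                           seed = sample.int(1e6, 1))
    f <- fit_curve(simulate_concentration_response(spec))
    bm <- benchmark_concentration(f, "EC10")
    truth <- ec50 / (top / 10 - 1)^(1 / hill)
    (bm$benchmark - truth) / truth
  })
  expect_lt(stats::median(abs(errs), na.rm = TRUE), 0.16)
  expect_lt(abs(stats::median(errs, na.rm = TRUE)), 0.05)  # no bias
})

test_that("simulated oxidation has the requested TK-Ratio structure", {
  ex <- simulate_oxidation(true_tk = 2.5, cv = 0, seed = 1)
  expect_equal(tk_ratio(ex$x_before, ex$x_after), 2.5, tolerance = 1e-12)
  expect_equal(ex$se_before, 0)
  expect_identical(simulate_oxidation(1.3, cv = 0.1, seed = 7),
                   simulate_oxidation(1.3, cv = 0.1, seed = 7))
  # law of large numbers: expected ratio equals true_tk
  set.seed(11)
  tks <- vapply(1:1000, function(i) {
    ex <- simulate_oxidation(true_tk = 1, cv = 0.1, n_reps = 2,
                             seed = sample.int(1e6, 1))
    tk_ratio(ex$x_before, ex$x_after)
  }, numeric(1))
  expect_lt(abs(mean(tks) - 1), 0.03)
})

test_that("the packaged panel matches the printed summary values", {
  panel <- load_table1_fixture()
  expect_equal(nrow(panel), 27L)
  expect_false(anyDuplicated(panel$compound) > 0)
  get <- function(id, col) panel[[col]][panel$compound == id]
  expect_equal(get("BPA", "ec10_eralpha"), 3.70e-7)
  expect_equal(get("TBBPA", "ec10_pparg"), 8.48e-8)
  expect_true(is.na(get("BADGE", "emax_eralpha")))
  expect_true(is.na(get("BADGE", "ec10_eralpha")))
  expect_equal(get("BPA", "ic10_median"), 7.00e-5)
  expect_equal(get("BPA", "sigma_sr_score"), 1.54)
  expect_equal(get("BPT", "emax_eralpha"), 80)
  expect_equal(get("BPS", "emax_eralpha"), 66)
  expect_equal(get("t-TMCD", "log_dlipw"), 1.43)
  expect_true(all(panel$alpha_neutral_pct >= 0 &
                    panel$alpha_neutral_pct <= 100))
})

test_that("the panel round-trips through CSV including censored cells", {
  panel <- load_table1_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(panel, path, na = "")
  back <- readr::read_csv(path, col_types = readr::cols(
    compound = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(panel))
})

test_that("SMILES fixture covers the full panel", {
  smi <- load_smiles_fixture()
  panel <- load_table1_fixture()
  expect_setequal(smi$id, panel$compound)
})
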