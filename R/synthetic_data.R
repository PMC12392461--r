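#' Specification for a synthetic concentration-response experiment
#'
#' Describes one compound x assay curve for the generator: the true
#' log-logistic parameters, the dilution design and the replicate noise.
#' Defaults mirror a typical reporter-gene screen: 12 concentrations in a
#' two-fold dilution series, 3 replicates, Gaussian replicate noise with SD
#' 5 on the reference-normalized % scale.
#'
#' @param true_top True curve maximum (% of reference maximum, or IR - 1
#'   amplitude for induction-ratio curves).
#' @param true_ec50 True EC50 in mol/L.
#' @param true_hill True Hill slope (> 0).
#' @param n_concentrations Number of tested concentrations.
#' @param dilution Dilution factor between consecutive concentrations.
#' @param n_replicates Technical replicates per concentration.
#' @param noise_sd Gaussian noise SD on the response scale.
#' @param cmax Highest tested concentration (mol/L); default `50 * true_ec50`
#'   so the series brackets the curve.
#' @param response_scale `"percent_effect"`, `"percent_inhibition"` or
#'   `"induction_ratio"`.
#' @param noise `"gaussian"` (default) or `"lognormal"` (multiplicative).
#' @param compound_id,assay_id Labels carried into the output.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(true_top, true_ec50, true_hill = 1,
                           n_concentrations = 12, dilution = 2,
                           n_replicates = 3, noise_sd = 5,
                           cmax = 50 * true_ec50,
                           response_scale = c("percent_effect",
                                              "percent_inhibition",
                                              "induction_ratio"),
                           noise = c("gaussian", "lognormal"),
                           compound_id = "synthetic", assay_id = "assay",
                           seed = 1L) {
  response_scale <- match.arg(response_scale)
  noise <- match.arg(noise)
  stopifnot(true_top > 0, true_ec50 > 0, true_hill > 0,
            n_concentrations >= 2, dilution > 1, n_replicates >= 1,
            noise_sd >= 0, cmax > 0)
  structure(list(true_top = true_top, true_ec50 = true_ec50,
                 true_hill = true_hill,
                 n_concentrations = as.integer(n_concentrations),
                 dilution = dilution, n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, cmax = cmax,
                 response_scale = response_scale, noise = noise,
                 compound_id = compound_id, assay_id = assay_id,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Simulate concentration-response points
#'
#' Draws responses as the log-logistic mean plus i.i.d. noise over a
#' geometric concentration series. Noise is additive Gaussian on the
#' response scale by default (a multiplicative lognormal option exists).
#' Simulated responses are truncated at physical bounds where the scale has
#' them: inhibition is clamped to `[0, 100]` and induction ratios to
#' `>= 0`; reference-normalized effect responses may go negative, as real
#' normalized reporter data do.
#'
#' @param spec A [generator_spec()].
#' @return Tibble of points: `compound_id`, `assay_id`, `concentration`
#'   (mol/L), `response`, `response_scale`, `replicate`.
#' @export
simulate_concentration_response <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  conc <- spec$cmax / spec$dilution^(seq_len(spec$n_concentrations) - 1)
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      concentration = conc)
  mu <- spec$true_top /
    (1 + (spec$true_ec50 / grid$concentration)^spec$true_hill)
  if (spec$response_scale == "induction_ratio") mu <- mu + 1
  y <- if (spec$noise == "lognormal") {
    mu * stats::rlnorm(nrow(grid), meanlog = 0,
                       sdlog = spec$noise_sd / 100)
  } else {
    mu + stats::rnorm(nrow(grid), sd = spec$noise_sd)
  }
  y <- switch(spec$response_scale,
              percent_inhibition = pmin(pmax(y, 0), 100),
              induction_ratio = pmax(y, 0),
              y)
  tibble::tibble(compound_id = spec$compound_id, assay_id = spec$assay_id,
                 concentration = grid$concentration, response = y,
                 response_scale = spec$response_scale,
                 replicate = grid$replicate)
}

#' Simulate an oxidation experiment with a known TK-Ratio
#'
#' Benchmark concentrations before and after a simulated phase-I oxidation
#' are drawn as lognormal replicates around `x_baseline * true_tk` and
#' `x_baseline`, with mean corrections chosen so that the expected
#' before/after ratio equals `true_tk`. Replicate means and standard errors
#' are returned as one oxidation-experiment row.
#'
#' @param true_tk True TK-Ratio (> 0).
#' @param cv Coefficient of variation of a single replicate (>= 0).
#' @param n_reps Number of replicates (default 2, the usual design for this
#'   assay).
#' @param seed Integer seed.
#' @param x_baseline Benchmark concentration after oxidation, mol/L.
#' @param true_c_parent_ratio True parent-concentration ratio (default 1).
#' @param compound_id,endpoint Labels carried into the output.
#' @return One-row tibble with the oxidation-experiment fields
#'   (`x_before`, `se_before`, `x_after`, `se_after`, `c_parent_before`,
#'   `c_parent_after`).
#' @export
simulate_oxidation <- function(true_tk, cv, n_reps = 2, seed = 1L,
                               x_baseline = 1e-5, true_c_parent_ratio = 1,
                               compound_id = "synthetic",
                               endpoint = "cytotoxicity") {
  stopifnot(true_tk > 0, cv >= 0, n_reps >= 1)
  set.seed(seed)
  sdlog <- sqrt(log1p(cv^2))
  # meanlog offsets make E[before] * E[1/after] == true_tk
  before <- x_baseline * true_tk *
    stats::rlnorm(n_reps, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  after <- x_baseline *
    stats::rlnorm(n_reps, meanlog = +sdlog^2 / 2, sdlog = sdlog)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  tibble::tibble(compound_id = compound_id, endpoint = endpoint,
                 x_before = mean(before), se_before = se(before),
                 x_after = mean(after), se_after = se(after),
                 c_parent_before = 1,
                 c_parent_after = true_c_parent_ratio)
}

#' Load the packaged 27-compound study panel
#'
#' Physicochemical descriptors (fraction neutral, log Kow, log Dlipw),
#' median cytotoxicity IC10, per-assay effect benchmarks (ERalpha, PPARgamma,
#' AhR, ARE, MMP, NOI), maximum efficacies and the published cumulative
#' SR-Scores for BPA and its 26 alternatives, exactly as printed in the
#' study's summary table. Empty cells are censored benchmarks (no effect at
#' noncytotoxic concentrations) and load as `NA`.
#'
#' @return Tibble with one row per compound.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_panel.csv", package = "bpalt",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    compound = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Load reference-agonist benchmarks
#'
#' Benchmark concentrations of the assay reference agonists (estradiol for
#' ERalpha, rosiglitazone for PPARgamma) used for cross-compound potency
#' comparisons.
#'
#' @return Tibble with columns `compound`, `assay`, `ec10`, `emax_pct`,
#'   `role`.
#' @export
load_reference_benchmarks <- function() {
  path <- system.file("extdata", "reference_benchmarks.csv",
                      package = "bpalt", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    compound = readr::col_character(), assay = readr::col_character(),
    ec10 = readr::col_double(), emax_pct = readr::col_double(),
    role = readr::col_character()
  ), progress = FALSE)
}

#' Load the curated SMILES set for the study compounds
#'
#' Structures keyed to the panel's compound names, curated for this package
#' (the study does not print SMILES). The two TMCD entries share a
#' constitution and differ only in stereochemistry.
#'
#' @return Tibble with columns `id`, `smiles`.
#' @export
load_smiles_fixture <- function() {
  path <- system.file("extdata", "bpa_smiles_curated.tsv", package = "bpalt",
                      mustWork = TRUE)
  read_smiles_file(path)
}
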