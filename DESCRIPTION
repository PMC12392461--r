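Package: bpalt
Title: Comparative In Vitro Hazard Assessment of Bisphenol A Alternatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative in vitro hazard assessment of bisphenol A
    (BPA) and its substitution candidates. Fits log-logistic
    concentration-response curves and derives benchmark concentrations (EC10,
    IC10, EC_IR1.5) with cytotoxicity masking; predicts baseline (narcosis)
    cytotoxicity from liposome-water partitioning; computes relative effect
    potencies (REP), Toxic Ratios (TR), Specificity Ratios (SR) with a
    baseline-toxicity fallback, the sigmoidal SR-Score and its cumulative sum
    across an assay battery; quantifies metabolic activation after simulated
    phase-I oxidation (TK-Ratio with propagated standard error,
    parent-concentration ratio); and groups compounds by ECFP4/Tanimoto
    structural similarity. Includes a synthetic bioassay-data generator and a
    packaged physicochemical/effect-concentration panel for the 27 study
    compounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    minpack.lm,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
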