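---
title: "Methods: from concentration–response curves to substitution verdicts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from concentration-response curves to substitution verdicts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpalt)
```

`bpalt` turns tidy in vitro bioassay measurements for a panel of bisphenol A
(BPA) alternatives into a comparative hazard profile. This vignette is the
package's own account of the models it fits, the conventions it adopts where
several were defensible, and what its synthetic-data tests do and do not
demonstrate about real data.

## Concentration–response model

Effect and cytotoxicity curves are described by a three-parameter
log-logistic,

$$y(c) = \frac{top}{1 + (EC_{50}/c)^{h}},$$

with the bottom fixed at 0 and `top`, `EC50` and the Hill slope `h` free.
The free `top` is essential: most ERα-active bisphenols are *partial*
agonists (fitted maxima of roughly 12–80% of the reference agonist's
maximum), so constraining the asymptote to 100 would distort both potency
and efficacy. Responses are expected on a scale where the assay's reference
compound (estradiol for ERα, rosiglitazone for PPARγ) reaches 100;
cytotoxicity is fitted on the % inhibition scale (`100 - viability`), and
oxidative-stress data on the induction-ratio-minus-1 scale.

Fitting is nonlinear least squares by Levenberg–Marquardt
(`minpack.lm::nlsLM`) in log10-concentration space, i.e. on
`top / (1 + 10^(h (log10 EC50 - log10 c)))`. Starting values are the
plateau mean for `top`, the first concentration reaching half of it for
`log10 EC50`, and `h = 1`; box constraints keep `h` in `[0.05, 15]` and
`top > 0`. Homoscedastic Gaussian error is assumed, so ordinary least
squares is the maximum-likelihood fit; replicates enter as independent
points, which for a balanced design is equivalent to fitting replicate
means. Non-convergence is not an error: it produces a censored benchmark
with a diagnostic flag, because in screening practice a curve that cannot
be fitted is a curve without a derivable benchmark.

### Benchmark concentrations and censoring

Benchmarks are *absolute-threshold* inversions of the fitted curve:

- **EC10** — the concentration where the fitted response equals 10 on the
  reference-normalized scale, i.e. 10% of the *reference compound's*
  maximum, not 10% of the compound's own `top`. For a partial agonist with
  `top = 38` this sits at `EC50/(38/10 - 1)`, well below the EC50. The two
  definitions coincide only for full agonists, and the absolute convention
  is the one that makes potencies comparable across compounds with
  different efficacies.
- **IC10** — the same inversion at 10% inhibition.
- **EC_IR1.5** — the concentration where the induction ratio crosses 1.5.
  By default this comes from a zero-intercept straight line fitted to the
  low-effect region (induction ratio ≤ 5), the conventional evaluation for
  this oxidative-stress assay where responses rarely saturate; a
  log-logistic alternative is available via `fit_curve(model =)`.

A benchmark is right-censored (`NA`, carried as `"> c_max"` in CSV) when
the fitted `top` does not reach the threshold, when the fit fails, or when
the inverted concentration exceeds the highest tested concentration.
Censored benchmarks are *excluded* from every downstream ratio — they are
never imputed as zero or as `c_max` — and an endpoint is "active" exactly
when its benchmark is uncensored.

Standard errors of benchmarks are first-order (delta-method) propagations
of the fit covariance through the inversion formula, with a central-
difference gradient in `(top, log10 EC50, h)`. A bootstrap would be more
faithful near censoring boundaries but adds two orders of magnitude of
cost for little gain at the panel's typical noise level.

### Cytotoxicity masking

Before an effect curve is fitted, concentrations at or above the
cytotoxicity IC10 are removed (`mask_cytotoxic()`, strict `<` threshold):
responses measured in dying cells reflect cytotoxic burst activation, not
receptor pharmacology. A censored IC10 masks nothing. Masking can empty a
dataset, in which case the effect benchmark is censored downstream — a
deliberate propagation, not an error.

## Baseline toxicity

Nonspecific (narcosis-type) cytotoxicity is predicted from membrane
partitioning alone:

$$IC_{10,baseline} = \frac{0.026\ \mathrm{mol/L_{membrane}}}{D_{lipw}}
\left(1 + D_{BSAw}\,VF_{protein} + D_{lipw}\,VF_{lipid}\right),$$

where 0.026 mol/L membrane is the critical membrane burden, uniform across
chemicals and cell types, `D_lipw` and `D_BSAw` are linear-scale
liposome–water and BSA–water distribution ratios, and the `VF` terms are
volume fractions of protein and lipid in the exposure medium (L/L). Both
volume fractions default to **zero** — the pure-membrane limit — because
assay-medium compositions are protocol-specific and should be supplied
explicitly (`assay_medium()`); with a protein-rich medium the correction
can shift the prediction by an order of magnitude, which is why
medium-corrected Toxic Ratios cannot be reproduced from descriptor tables
alone.

Speciation uses Henderson–Hasselbalch for mono- and diprotic acids at pH
7.4 (physiological default): the neutral fraction is
`1/(1 + 10^(pH - pKa1))`, resp.
`1/(1 + 10^(pH - pKa1) + 10^(2 pH - pKa1 - pKa2))`. The optional
`lipw_from_kow()` helper maps log K~ow~ to log D~lipw~ with a
user-supplied linear map and an anion discount (log-units by which the
charged species partitions more weakly); it deliberately ships **no
default coefficients**, since calibration constants for such maps are
system-specific and silently inventing them would masquerade as measured
chemistry.

## Ratio metrics and scores

With benchmarks in hand, the comparative metrics are simple quotients with
strict censoring discipline (any censored operand ⇒ undefined result,
flagged `NA`):

- `TR = IC10_baseline / IC10`: TR ≥ 10 flags specific cytotoxicity
  mechanisms, 0.1 < TR < 10 is baseline, TR ≤ 0.1 suggests losses or
  reduced bioavailability. The ≥ boundary is inclusive.
- `SR = IC10 / EC`, preferring the experimental IC10 and falling back to
  the baseline prediction when the IC10 is censored (`sr_source` records
  which). SR ≈ 1 means the "effect" occurs at cytotoxic concentrations.
- `REP = EC10_ref / EC10_test` (> 1: more potent than the reference).
- `SR-Score = 1/(1 + e^{-(SR-5)})`: a sigmoid with midpoint 5, chosen so
  SR = 1 maps to ≈ 0.018 (not specific), SR = 5 to exactly 0.5, SR = 10 to
  ≈ 0.9933. The asymptote is **not** clipped to 1; "an SR of 10 scores 1"
  is rounding, and in double precision the sigmoid saturates to exactly
  1.0 for SR ≳ 42.
- `Σ-SR-Score`: the sum of SR-Scores over *active* endpoints; inactive
  endpoints contribute nothing, so the score is bounded by the battery
  size (6 here).
- Substitution rule: a candidate is `regrettable` iff its Σ-SR-Score is
  ≥ the reference compound's **and** its cytotoxicity REP (ratio of median
  IC10s) exceeds 1. Equality on the Σ axis counts against the candidate.

One consequence the pipeline makes explicit (`sr_basis = "median_ic10"`):
when SRs are computed from a *median* IC10 across cell lines rather than
the assay-matched cell line's own IC10, per-assay SRs — and hence
Σ-SR-Scores — differ from values computed per cell line. The packaged
panel carries only the median, so its SRs reproduce the qualitative
pattern (e.g. ERα SR > 100 for Bz, BP-MIBK, BPAF) but not per-cell-line
magnitudes, and the published Σ column in the fixture is carried as data,
not recomputed.

## Metabolic activation

The oxidation module compares benchmarks before and after an abiotic
cytochrome-P450-mimicking (porphyrin/H₂O₂) treatment:
`TK = x_before / x_after` (> 1: the oxidized mixture is more potent) with
the first-order SEM

$$\sqrt{(SE_b/x_a)^2 + (x_b\,SE_a/x_a^2)^2},$$

taken on the linear concentration scale, as the inputs are. The SEM is
dimensionless and invariant under common rescaling of all four arguments;
against Monte-Carlo propagation it is accurate to well within 10% for
input CVs up to ~10% (at larger CVs the ratio distribution grows heavy
tails and a first-order formula undercovers — with the n = 2 replicates
typical of this assay, SEs are crude anyway, and the module accepts them
as given). `C_parent`-Ratio = concentration after / before quantifies
parent turnover. The interpreter labels TK > 2 as a more-toxic mixture and
adds an `inconsistent` flag when that happens with essentially no parent
loss (C_parent-Ratio ≥ 0.9, configurable): either a trace-level, very
potent metabolite or an inaccurate IC10.

## Structural grouping

Compounds are grouped by Morgan/ECFP4 circular fingerprints. SMILES are
canonicalized with OpenBabel first, so notation variants of the same
molecule hash identically, then parsed into a heavy-atom graph. Initial
atom invariants are (atomic number, heavy-atom degree, hydrogen count,
formal charge, ring membership — ring bonds being non-bridge edges);
neighborhoods are iteratively re-hashed to radius 2 with
(bond-order, neighbor-id) pairs in sorted order, and all iteration
identifiers are folded onto 1024 bits, the common ECFP4 default.
Stereochemistry is not encoded — the two TMCD stereoisomer entries in the
panel share one fingerprint by construction. Distances are Tanimoto on set
bits; grouping is `hclust` with average linkage (unstated in the source
workflow; complete and Ward-D2 are available) cut at k = 5. Partition
comparisons use a label-permutation-invariant check. On the curated
27-compound SMILES set the cut separates the cyclobutanediols and the
sulfonylurea developers from the bisphenol scaffolds; exact reproduction
of every published group boundary is a soft check, since the curated
structures, fingerprint engine and linkage all differ from the original
workflow's unstated choices.

## The synthetic-data generator

`generator_spec()` + `simulate_concentration_response()` emulate a
reporter-gene screen: a geometric dilution series (default 12
concentrations, 2× dilution, highest at 50× the true EC50), 3 replicates,
and i.i.d. additive Gaussian noise with SD 5 on the normalized-% scale
(a multiplicative lognormal option exists). Truncation follows the physics
of each scale: inhibition is clamped to [0, 100] and induction ratios to
≥ 0, while reference-normalized effect responses are left untruncated
because real normalized reporter signals do go below zero. Oxidation
experiments are simulated as lognormal replicate draws whose mean-log
offsets make the expected before/after ratio equal the requested TK-Ratio
exactly.

What the generator does **not** emulate: plate effects and edge wells,
heteroscedastic detector noise, solubility ceilings and precipitation,
receptor kinetics, or cell-growth dynamics. Passing recovery tests
therefore demonstrates that the estimator chain is correct and efficient
under the stated error model — not that real curves of this panel carry
that error model.

### Precision limits of EC10 recovery

A point this package states explicitly rather than hiding: under the
default design (12 two-fold dilutions, 3 replicates, additive SD 5), the
Cramér–Rao bound for the inverted EC10 of a favorable curve
(top = 80, h = 1) is ≈ 16% relative SE — implying a median absolute
relative error around 11% for *any* unbiased estimator, and more for
shallower or lower-efficacy curves. Repositioning the dilution window
changes this by under two points. The package's fit is unbiased (median
signed error ≈ 0) and sits at this floor; its recovery tests assert
unbiasedness and precision at the bound. Emax recovery is much better
conditioned (SE ≈ 2 percentage points under the same design), which is why
efficacy round-trips to within ±5 points reliably.

## Numerical conventions and degenerate inputs

- Benchmark inversion uses the closed form `EC50/(top/y - 1)^(1/h)`; `top`
  ≤ threshold is censoring, not error.
- Ratios reported in summaries round to 2 significant figures; scores to
  2 decimals (`report_round()`).
- `median_ic10()` drops censored values with a logged count; all-censored
  input yields a censored median.
- Empty fingerprints (no set bits) are warned about and placed at distance
  1 from everything except an identical empty vector (distance 0).
- An empty benchmark table is valid pipeline input: every compound appears
  once, all endpoints inactive, Σ-SR-Score 0.
- All simulation and clustering entry points are deterministic under a
  fixed seed; the pipeline writes byte-identical outputs on reruns.

Test problem sizes were chosen to keep the full suite in seconds:
recovery properties use 50 simulated curves of 36 points each, Monte-Carlo
SEM oracles use 10⁵ draws, and clustering runs on the full 27-compound
panel.

## Known limitations

- The packaged panel carries median IC10s only; per-cell-line SRs, TRs
  with medium corrections, and therefore exact published Σ-SR-Scores are
  out of reach of the fixture by construction.
- The EC_IR1.5 linear evaluation assumes approximate low-dose linearity of
  the induction ratio; strongly sigmoidal induction data should use the
  log-logistic option.
- Hydrogen counts in the fingerprinting graph come from a standard valence
  model (B, C, N, O, Si, P, S, halogens); exotic valences or charged
  organometallics are rejected rather than silently mis-hashed.
- The substitution rule is a screen, not a risk assessment: it weighs
  breadth of specific in vitro activity and relative cytotoxic potency,
  nothing else.
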