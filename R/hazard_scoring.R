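#' Relative effect potency (REP)
#'
#' Ratio of the reference compound's benchmark concentration to the test
#' compound's, \eqn{REP = EC_{10,ref} / EC_{10,test}}; values above 1 mean
#' the test compound is more potent than the reference. Censored inputs
#' (`NA`) yield an undefined (`NA`) REP rather than zero.
#'
#' @param ec_reference,ec_test Benchmark concentrations in mol/L (> 0), `NA`
#'   when censored. Vectorized.
#' @return Unitless potency ratio.
#' @examples
#' relative_potency(3.70e-7, 1.43e-8)   # ~26: test compound more potent
#' @export
relative_potency <- function(ec_reference, ec_test) {
  check_positive_or_na(ec_reference, "ec_reference")
  check_positive_or_na(ec_test, "ec_test")
  ec_reference / ec_test
}

#' Toxic Ratio (TR)
#'
#' Ratio of the predicted baseline cytotoxicity to the experimental IC10,
#' \eqn{TR = IC_{10,baseline} / IC_{10}}. TR >= 10 flags cytotoxicity driven
#' by specific mechanisms beyond membrane narcosis; 0.1 < TR < 10 is the
#' baseline range.
#'
#' @param ic10_baseline Predicted baseline IC10 (mol/L, > 0).
#' @param ic10_experimental Experimental IC10 (mol/L, > 0), `NA` censored.
#' @return Unitless TR (`NA` when the experimental IC10 is censored).
#' @export
toxic_ratio <- function(ic10_baseline, ic10_experimental) {
  check_positive_or_na(ic10_baseline, "ic10_baseline")
  check_positive_or_na(ic10_experimental, "ic10_experimental")
  ic10_baseline / ic10_experimental
}

#' @rdname toxic_ratio
#' @param tr Toxic Ratio (> 0).
#' @return `classify_tr()` returns `"specific"` (TR >= 10), `"baseline"`
#'   (0.1 < TR < 10) or `"below_baseline"` (TR <= 0.1).
#' @export
classify_tr <- function(tr) {
  stopifnot(all(tr > 0, na.rm = TRUE))
  dplyr::case_when(
    is.na(tr) ~ NA_character_,
    tr >= 10 ~ "specific",
    tr > 0.1 ~ "baseline",
    TRUE ~ "below_baseline"
  )
}

#' Specificity Ratio (SR) with baseline fallback
#'
#' How far a specific effect lies below cytotoxic concentrations:
#' \eqn{SR = IC_{10} / EC}, where EC is the effect benchmark (EC10 or
#' EC_IR1.5). SR near 1 means the effect occurs at cytotoxic concentrations
#' (likely nonspecific burst activation). When no experimental IC10 is
#' available the predicted baseline IC10 is used instead
#' (\eqn{SR_{baseline}}).
#'
#' @param ec Effect benchmark in mol/L (> 0); `NA` when the endpoint is
#'   inactive (censored), in which case no SR is defined.
#' @param ic10 Experimental cytotoxicity IC10 (mol/L), `NA` when censored.
#' @param ic10_baseline Predicted baseline IC10 (mol/L), `NA` if unavailable.
#' @return A tibble with columns `sr` and `sr_source` (`"cytotoxicity"`,
#'   `"baseline"` or `"none"`). Vectorized.
#' @export
specificity_ratio <- function(ec, ic10 = NA_real_, ic10_baseline = NA_real_) {
  n <- max(length(ec), length(ic10), length(ic10_baseline))
  ec <- rep_len(ec, n); ic10 <- rep_len(ic10, n)
  ic10_baseline <- rep_len(ic10_baseline, n)
  check_positive_or_na(ec, "ec")
  check_positive_or_na(ic10, "ic10")
  check_positive_or_na(ic10_baseline, "ic10_baseline")
  sr <- dplyr::case_when(
    is.na(ec) ~ NA_real_,
    !is.na(ic10) ~ ic10 / ec,
    !is.na(ic10_baseline) ~ ic10_baseline / ec,
    TRUE ~ NA_real_
  )
  source <- dplyr::case_when(
    is.na(ec) ~ "none",
    !is.na(ic10) ~ "cytotoxicity",
    !is.na(ic10_baseline) ~ "baseline",
    TRUE ~ "none"
  )
  tibble::tibble(sr = sr, sr_source = source)
}

#' SR-Score: sigmoidal transform of the Specificity Ratio
#'
#' Rescales an SR onto (0, 1) with midpoint 5:
#' \deqn{SR\text{-}Score = \frac{1}{1 + e^{-(SR - 5)}}.}
#' An SR of 1 maps to ~0.018 (reported as ~0), SR = 5 to exactly 0.5 and
#' SR = 10 to ~0.993 (reported as ~1). The asymptote is not clipped to 1.
#'
#' @param sr Specificity Ratio (> 0). Vectorized; `NA` passes through.
#' @return SR-Score in (0, 1).
#' @export
sr_score <- function(sr) {
  check_positive_or_na(sr, "sr")
  stats::plogis(sr - 5)
}

#' Cumulative SR-Score across the assay battery
#'
#' Sum of SR-Scores over all active endpoints; inactive endpoints (no effect
#' benchmark, `NA` SR) contribute nothing. Bounded by the battery size (six
#' if all six bioassays are specifically activated).
#'
#' @param srs Specificity Ratios of the active endpoints (`NA` entries are
#'   dropped as inactive).
#' @return Unitless sum in `[0, length(srs)]`; 0 for an empty input.
#' @export
cumulative_sr_score <- function(srs) {
  srs <- srs[!is.na(srs)]
  if (!length(srs)) return(0)
  sum(sr_score(srs))
}

#' Substitution classification
#'
#' A substitute is flagged as a regrettable substitution when its Cumulative
#' SR-Score is equal to or higher than the reference compound's and its
#' cytotoxicity-based relative potency exceeds 1 (i.e. it is both at least
#' as broadly specifically active and more cytotoxic than the compound it
#' replaces).
#'
#' @param sigma Cumulative SR-Score of the candidate.
#' @param sigma_reference Cumulative SR-Score of the reference compound.
#' @param rep_ic10 Cytotoxicity REP vs the reference (median IC10 ratio).
#' @return `"regrettable"` or `"not_flagged"`. Vectorized.
#' @export
classify_substitute <- function(sigma, sigma_reference, rep_ic10) {
  stopifnot(all(sigma >= 0, na.rm = TRUE),
            all(sigma_reference >= 0, na.rm = TRUE),
            all(rep_ic10 >= 0, na.rm = TRUE))
  ifelse(!is.na(sigma) & !is.na(rep_ic10) &
           sigma >= sigma_reference & rep_ic10 > 1,
         "regrettable", "not_flagged")
}

check_positive_or_na <- function(x, name) {
  if (any(x <= 0, na.rm = TRUE)) {
    stop("`", name, "` must be > 0 (use NA for censored values)",
         call. = FALSE)
  }
  invisible(x)
}
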