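#' Toxicokinetic ratio (TK-Ratio) of benchmark concentrations
#'
#' Ratio of the benchmark concentration before simulated phase-I oxidation to
#' the one after, \eqn{TK = x_{before} / x_{after}}. A TK-Ratio of 1 means
#' the reaction mixture is as potent as the parent compound; > 1 indicates
#' elevated potency after oxidation (metabolic activation), < 1 a loss of
#' potency (detoxification).
#'
#' @param x_before,x_after Benchmark concentrations (mol/L, > 0), `NA` when
#'   censored (TK-Ratio then undefined). Vectorized.
#' @return Unitless TK-Ratio.
#' @export
tk_ratio <- function(x_before, x_after) {
  check_positive_or_na(x_before, "x_before")
  check_positive_or_na(x_after, "x_after")
  x_before / x_after
}

#' First-order standard error of the TK-Ratio
#'
#' Error propagation for the ratio of two independently estimated benchmark
#' concentrations:
#' \deqn{SEM = \sqrt{\left(\frac{SE_{before}}{x_{after}}\right)^2 +
#'   \left(\frac{x_{before}\,SE_{after}}{x_{after}^2}\right)^2}.}
#' SEs are taken on the linear concentration scale, as are the inputs.
#'
#' @param x_before,x_after Benchmark concentrations (mol/L, > 0).
#' @param se_before,se_after Their standard errors (mol/L, >= 0).
#' @return SEM of the TK-Ratio (unitless). Vectorized.
#' @export
tk_ratio_sem <- function(x_before, se_before, x_after, se_after) {
  check_positive_or_na(x_before, "x_before")
  check_positive_or_na(x_after, "x_after")
  stopifnot(all(se_before >= 0, na.rm = TRUE), all(se_after >= 0, na.rm = TRUE))
  sqrt((se_before / x_after)^2 + (x_before * se_after / x_after^2)^2)
}

#' Parent-compound concentration ratio after oxidation
#'
#' \eqn{C_{parent}\text{-Ratio} = C_{parent,after} / C_{parent,before}}:
#' 1 indicates no oxidation of the parent compound, values below 1 partial
#' degradation or other losses.
#'
#' @param c_after Parent concentration after oxidation (>= 0, any consistent
#'   unit).
#' @param c_before Parent concentration before oxidation (> 0, same unit).
#' @return Unitless ratio in `[0, Inf)`. Vectorized.
#' @export
c_parent_ratio <- function(c_after, c_before) {
  stopifnot(all(c_after >= 0, na.rm = TRUE))
  check_positive_or_na(c_before, "c_before")
  c_after / c_before
}

#' Interpret an oxidation experiment
#'
#' Classifies the cytotoxicity TK-Ratio: a more than 2-fold increase in
#' cytotoxicity after oxidation (`tk > 2`) labels the reaction mixture
#' `"more-toxic-mixture"`, otherwise `"similar-or-detoxified"`. When the
#' mixture became more toxic although the parent compound was essentially
#' not consumed (C_parent-Ratio >= `no_oxidation_min`), the case is
#' additionally flagged inconsistent: either a very potent metabolite formed
#' from a small turnover, or the IC10s are inaccurate.
#'
#' @param tk_cytotoxicity Cytotoxicity TK-Ratio.
#' @param c_parent_ratio Parent concentration ratio after/before.
#' @param fold_threshold TK-Ratio above which the mixture counts as more
#'   toxic (default 2).
#' @param no_oxidation_min C_parent-Ratio at or above which the parent is
#'   considered unoxidized (default 0.9, i.e. a 10% tolerance).
#' @return Tibble with columns `label` and `inconsistent`. Vectorized.
#' @export
interpret_oxidation <- function(tk_cytotoxicity, c_parent_ratio,
                                fold_threshold = 2, no_oxidation_min = 0.9) {
  label <- ifelse(tk_cytotoxicity > fold_threshold,
                  "more-toxic-mixture", "similar-or-detoxified")
  inconsistent <- tk_cytotoxicity > fold_threshold &
    !is.na(c_parent_ratio) & c_parent_ratio >= no_oxidation_min
  tibble::tibble(label = label, inconsistent = inconsistent)
}

#' Summarize a table of oxidation experiments
#'
#' Computes TK-Ratio, its propagated SEM, the C_parent-Ratio and the
#' interpretation label for each row of an oxidation-experiment table.
#'
#' @param experiments Tibble with columns `compound_id`, `endpoint`,
#'   `x_before`, `se_before`, `x_after`, `se_after`, `c_parent_before`,
#'   `c_parent_after`.
#' @return The input with appended columns `tk_ratio`, `tk_sem`,
#'   `c_parent_ratio`, `label`, `inconsistent` (interpretation uses the
#'   row's own TK-Ratio; for effect endpoints it describes potency change
#'   rather than cytotoxicity).
#' @export
oxidation_summary <- function(experiments) {
  need <- c("compound_id", "endpoint", "x_before", "se_before", "x_after",
            "se_after", "c_parent_before", "c_parent_after")
  if (!all(need %in% names(experiments))) {
    stop("`experiments` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tk <- tk_ratio(experiments$x_before, experiments$x_after)
  sem <- tk_ratio_sem(experiments$x_before, experiments$se_before,
                      experiments$x_after, experiments$se_after)
  cpr <- c_parent_ratio(experiments$c_parent_after,
                        experiments$c_parent_before)
  dplyr::bind_cols(
    experiments,
    tibble::tibble(tk_ratio = tk, tk_sem = sem, c_parent_ratio = cpr),
    interpret_oxidation(tk, cpr)
  )
}
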