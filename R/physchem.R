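#' Fraction of neutral species of an acid at a given pH
#'
#' Henderson--Hasselbalch speciation for mono- and diprotic acids. The
#' fraction of the fully protonated (neutral) species governs how strongly an
#' ionizable compound partitions into membranes, and enters the
#' ionization-corrected liposome--water distribution ratio.
#'
#' @param pka_values Numeric vector of acid dissociation constants (pH units),
#'   sorted ascending. May be longer than `n_acidic`; only the first
#'   `n_acidic` values are used.
#' @param n_acidic Number of acidic protons considered (0, 1 or 2). Defaults
#'   to `length(pka_values)` capped at 2.
#' @param ph Assay pH. Default 7.4 (physiological).
#'
#' @return Fraction of neutral species in `[0, 1]`.
#' @examples
#' fraction_neutral(numeric(0), n_acidic = 0)       # 1
#' fraction_neutral(7.4)                            # 0.5 at pKa == pH
#' fraction_neutral(c(7.5, 8.2), n_acidic = 2)
#' @export
fraction_neutral <- function(pka_values, n_acidic = min(length(pka_values), 2L),
                             ph = 7.4) {
  stopifnot(is.numeric(ph), length(ph) == 1L)
  if (!n_acidic %in% 0:2) {
    stop("`n_acidic` must be 0, 1 or 2", call. = FALSE)
  }
  if (length(pka_values) < n_acidic) {
    stop("declared ", n_acidic, " acidic proton(s) but only ",
         length(pka_values), " pKa value(s) supplied", call. = FALSE)
  }
  if (n_acidic == 0L) return(1)
  pka <- sort(pka_values[seq_len(n_acidic)])
  denom <- 1 + 10^(ph - pka[1])
  if (n_acidic == 2L) denom <- denom + 10^(2 * ph - pka[1] - pka[2])
  1 / denom
}

#' Assay medium composition
#'
#' Volume fractions of protein and lipid in the exposure medium, used to
#' correct the nominal baseline-toxicity prediction for sorption to medium
#' constituents. Defaults are zero (pure-membrane limit); real media should
#' override them.
#'
#' @param vf_protein Volume fraction of protein in the medium (L/L).
#' @param vf_lipid Volume fraction of lipid in the medium (L/L).
#' @param ph Assay pH.
#' @return A list of class `assay_medium`.
#' @export
assay_medium <- function(vf_protein = 0, vf_lipid = 0, ph = 7.4) {
  stopifnot(vf_protein >= 0, vf_lipid >= 0, vf_protein + vf_lipid < 1)
  structure(list(vf_protein = vf_protein, vf_lipid = vf_lipid, ph = ph),
            class = "assay_medium")
}

#' Predicted baseline (narcosis) cytotoxicity IC10
#'
#' Nominal concentration causing 10% cytotoxicity by nonspecific membrane
#' accumulation, predicted from a critical membrane concentration of
#' 0.026 mol/L membrane that is uniform across chemicals and cell types:
#'
#' \deqn{IC_{10,baseline} = \frac{0.026}{D_{lipw}}
#'   (1 + D_{BSAw} VF_{protein} + D_{lipw} VF_{lipid})}
#'
#' With both medium volume fractions zero this reduces to `0.026 / d_lipw`.
#'
#' @param d_lipw Linear-scale liposome--water distribution ratio (> 0).
#' @param d_bsaw Linear-scale BSA--water distribution ratio (>= 0, default 0).
#' @param medium An [assay_medium()] giving protein/lipid volume fractions.
#' @return Predicted baseline IC10 in mol/L. Vectorized over `d_lipw`/`d_bsaw`.
#' @examples
#' baseline_ic10(1)              # 0.026 mol/L, pure-membrane limit
#' baseline_ic10(10^3.65)        # ~5.8e-6 mol/L
#' @export
baseline_ic10 <- function(d_lipw, d_bsaw = 0, medium = assay_medium()) {
  if (any(!is.finite(d_lipw) | d_lipw <= 0)) {
    stop("`d_lipw` must be finite and > 0", call. = FALSE)
  }
  stopifnot(all(d_bsaw >= 0))
  0.026 / d_lipw *
    (1 + d_bsaw * medium$vf_protein + d_lipw * medium$vf_lipid)
}

#' Ionization-corrected liposome-water distribution ratio from log Kow
#'
#' Optional helper mapping the octanol--water partition constant of the
#' neutral species onto a log liposome--water distribution ratio, with an
#' anion "discount": the charged species is assumed to partition
#' `anion_discount` log units more weakly than the neutral species. All
#' coefficients must be supplied explicitly; the function applies
#'
#' \deqn{\log D_{lipw} = \log_{10}\left(\alpha\,10^{s\,\log K_{ow}+b} +
#'   (1-\alpha)\,10^{s\,\log K_{ow}+b-\Delta}\right)}
#'
#' where `s`/`b` are the slope/intercept of the linear map and `Delta` the
#' anion discount. With the identity map and `alpha_neutral = 1` the input is
#' returned unchanged.
#'
#' @param log_kow log10 octanol--water partition constant (neutral species).
#' @param alpha_neutral Fraction of neutral species in `[0, 1]`.
#' @param slope,intercept Linear map applied to `log_kow` (no defaults hidden:
#'   identity is `slope = 1, intercept = 0`).
#' @param anion_discount Log-unit reduction in partitioning for the charged
#'   species (>= 0).
#' @return log10 liposome--water distribution ratio.
#' @export
lipw_from_kow <- function(log_kow, alpha_neutral, slope, intercept,
                          anion_discount) {
  if (any(alpha_neutral < 0 | alpha_neutral > 1)) {
    stop("`alpha_neutral` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(anion_discount >= 0)
  lk <- slope * log_kow + intercept
  log10(alpha_neutral * 10^lk + (1 - alpha_neutral) * 10^(lk - anion_discount))
}

#' Read or write a compound panel
#'
#' A compound panel is a tibble with one row per compound and columns
#' `id, log_kow, log_dlipw, log_dbsaw, pka1, pka2, alpha_neutral, smiles`.
#' Missing numeric values are empty cells in the CSV.
#'
#' @param path Path to a CSV file.
#' @return `read_compound_panel()` returns a tibble; `write_compound_panel()`
#'   returns `path` invisibly.
#' @export
read_compound_panel <- function(path) {
  panel <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    log_kow = readr::col_double(),
    log_dlipw = readr::col_double(),
    log_dbsaw = readr::col_double(),
    pka1 = readr::col_double(),
    pka2 = readr::col_double(),
    alpha_neutral = readr::col_double(),
    smiles = readr::col_character()
  ), progress = FALSE)
  validate_panel(panel)
  panel
}

#' @rdname read_compound_panel
#' @param panel A compound panel tibble.
#' @export
write_compound_panel <- function(panel, path) {
  validate_panel(panel)
  readr::write_csv(panel, path, na = "")
  invisible(path)
}

validate_panel <- function(panel) {
  if (anyNA(panel$id) || any(!nzchar(panel$id))) {
    stop("compound ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(panel$id)) {
    stop("compound ids must be unique within a panel", call. = FALSE)
  }
  a <- panel$alpha_neutral
  if (any(a < 0 | a > 1, na.rm = TRUE)) {
    stop("`alpha_neutral` must lie in [0, 1]", call. = FALSE)
  }
  invisible(panel)
}
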