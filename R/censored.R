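#' Censoring markers for benchmark concentrations
#'
#' Benchmarks that were not reached at the highest tested concentration are
#' right-censored and carried as `"> cmax"` strings in CSV exports, and as
#' `NA` with a recorded `cmax` in tibbles. These helpers round-trip between
#' the two representations.
#'
#' @param value Numeric benchmark (mol/L), `NA` when censored.
#' @param cmax Highest tested concentration (mol/L), used for the censoring
#'   marker.
#' @return `format_benchmark()` returns a character vector;
#'   `parse_benchmark()` a tibble with columns `value` and `censored`.
#' @examples
#' format_benchmark(c(3.7e-7, NA), cmax = 1.8e-2)
#' parse_benchmark(c("3.7e-07", ">1.8e-02", ""))
#' @export
format_benchmark <- function(value, cmax = NA_real_) {
  cmax <- rep_len(cmax, length(value))
  out <- sprintf("%.6g", value)
  cens <- is.na(value)
  out[cens] <- ifelse(is.na(cmax[cens]), "",
                      sprintf(">%.6g", cmax[cens]))
  out
}

#' @rdname format_benchmark
#' @param x Character vector of benchmark strings (`"3.7e-07"`, `">1.8e-02"`
#'   or empty).
#' @export
parse_benchmark <- function(x) {
  x <- trimws(x)
  censored <- grepl("^>", x) | x == "" | is.na(x)
  value <- suppressWarnings(as.numeric(x))
  value[censored] <- NA_real_
  cmax <- suppressWarnings(as.numeric(sub("^>", "", x)))
  cmax[!grepl("^>", x)] <- NA_real_
  tibble::tibble(value = value, censored = censored, cmax = cmax)
}
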