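ASSAY_IDS <- c("ERalpha", "PPARgamma", "AhR", "ARE", "MMP", "NOI")

#' Long benchmark table from a wide panel
#'
#' Pivots the per-assay benchmark columns of a panel in the packaged
#' summary-table layout (`ec10_eralpha`, `ec10_pparg`, `ec10_ahr`,
#' `ec_ir15_are`, `ec10_mmp`, `ec10_noi`) into a tidy benchmark table.
#'
#' @param panel Panel tibble, e.g. from [load_table1_fixture()].
#' @return Tibble `compound_id`, `assay_id`, `benchmark_type`, `benchmark`
#'   (`NA` = censored/no effect).
#' @export
fixture_benchmarks <- function(panel) {
  cols <- c(ERalpha = "ec10_eralpha", PPARgamma = "ec10_pparg",
            AhR = "ec10_ahr", ARE = "ec_ir15_are", MMP = "ec10_mmp",
            NOI = "ec10_noi")
  missing_cols <- setdiff(unname(cols), names(panel))
  if (length(missing_cols)) {
    stop("panel lacks benchmark column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    panel[, c("compound", unname(cols))],
    cols = -"compound", names_to = "col", values_to = "benchmark"
  )
  long$assay_id <- names(cols)[match(long$col, cols)]
  long$benchmark_type <- ifelse(long$assay_id == "ARE", "EC_IR1.5", "EC10")
  tibble::tibble(compound_id = long$compound, assay_id = long$assay_id,
                 benchmark_type = long$benchmark_type,
                 benchmark = long$benchmark)
}

#' Run the comparative hazard-assessment pipeline
#'
#' Composes the scoring stages over a compound panel: predicted baseline
#' IC10 from the liposome--water distribution ratio, Toxic Ratio against the
#' median experimental IC10, per-assay Specificity Ratios (experimental IC10
#' preferred, baseline fallback when it is censored), SR-Scores and their
#' cumulative sum, relative effect potencies against the reference compound,
#' and the substitution classification.
#'
#' SRs computed here use the panel's median IC10 across cell lines
#' (`sr_basis = "median_ic10"`); assay-matched per-cell-line IC10s, where
#' available, give different (published) SR values.
#'
#' @param panel Panel tibble with columns `compound`, `log_dlipw`,
#'   `ic10_median` (and the wide benchmark columns unless `benchmarks` is
#'   supplied).
#' @param benchmarks Optional tidy benchmark table as from
#'   [fixture_benchmarks()] or [fit_assay_table()] (columns `compound_id`,
#'   `assay_id`, `benchmark`). Defaults to `fixture_benchmarks(panel)`.
#' @param reference Reference compound id for REP (default `"BPA"`).
#' @param medium [assay_medium()] for the baseline prediction.
#' @param d_bsaw Linear-scale BSA--water distribution ratios (recycled);
#'   only relevant when the medium has a protein fraction.
#' @param out_dir Optional directory; when given, the endpoint table,
#'   profile table, heatmap matrix, scatter table, a provenance JSON sidecar
#'   and a decision log are written as CSV/JSON/text.
#' @return List of class `hazard_profiles`: `profiles` (one row per
#'   compound), `endpoints` (one row per compound x assay), `reference`,
#'   `log` (character vector of fallback/censoring decisions).
#' @export
run_pipeline <- function(panel, benchmarks = NULL, reference = "BPA",
                         medium = assay_medium(), d_bsaw = 0,
                         out_dir = NULL) {
  need <- c("compound", "log_dlipw", "ic10_median")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(panel$compound)) {
    stop("duplicated compound ids in panel", call. = FALSE)
  }
  if (!reference %in% panel$compound) {
    stop("reference compound '", reference, "' not in panel", call. = FALSE)
  }
  if (is.null(benchmarks)) benchmarks <- fixture_benchmarks(panel)
  bad <- !benchmarks$compound_id %in% panel$compound
  if (any(bad)) {
    stop("benchmark rows for unknown compound(s): ",
         paste(unique(benchmarks$compound_id[bad]), collapse = ", "),
         call. = FALSE)
  }

  prof <- tibble::tibble(
    compound_id = panel$compound,
    ic10_baseline = baseline_ic10(10^panel$log_dlipw, d_bsaw, medium),
    ic10_median = panel$ic10_median
  )
  prof$tr <- toxic_ratio(prof$ic10_baseline, prof$ic10_median)
  prof$tr_class <- classify_tr(prof$tr)

  # per-assay endpoint table: every compound x assay appears exactly once
  ep <- tidyr::expand_grid(compound_id = panel$compound,
                           assay_id = ASSAY_IDS)
  ep <- dplyr::left_join(ep, benchmarks, by = c("compound_id", "assay_id"))
  ep$benchmark_type[is.na(ep$benchmark_type)] <-
    ifelse(ep$assay_id[is.na(ep$benchmark_type)] == "ARE", "EC_IR1.5", "EC10")
  i <- match(ep$compound_id, prof$compound_id)
  sr <- specificity_ratio(ep$benchmark, prof$ic10_median[i],
                          prof$ic10_baseline[i])
  ep$sr <- sr$sr
  ep$sr_source <- sr$sr_source
  ep$sr_score <- ifelse(is.na(ep$sr), NA_real_, sr_score(ep$sr))
  ep$active <- !is.na(ep$benchmark)
  ep$sr_basis <- "median_ic10"

  ref_bm <- ep[ep$compound_id == reference, c("assay_id", "benchmark")]
  ep$rep <- relative_potency(
    ref_bm$benchmark[match(ep$assay_id, ref_bm$assay_id)], ep$benchmark)

  sig <- vapply(split(ep$sr, ep$compound_id)[panel$compound],
                cumulative_sr_score, numeric(1))
  prof$cumulative_sr_score <- unname(sig)
  prof$rep_ic10 <- relative_potency(
    prof$ic10_median[prof$compound_id == reference], prof$ic10_median)
  prof$category <- classify_substitute(
    prof$cumulative_sr_score,
    prof$cumulative_sr_score[prof$compound_id == reference],
    prof$rep_ic10)

  log <- c(
    sprintf("endpoint %s/%s: censored benchmark, inactive, no SR",
            ep$compound_id[!ep$active], ep$assay_id[!ep$active]),
    sprintf("endpoint %s/%s: censored IC10, SR from baseline prediction",
            ep$compound_id[ep$sr_source == "baseline"],
            ep$assay_id[ep$sr_source == "baseline"]),
    sprintf("compound %s: censored median IC10, TR/REP_IC10 undefined",
            prof$compound_id[is.na(prof$ic10_median)])
  )

  res <- structure(list(profiles = prof, endpoints = ep,
                        reference = reference, log = log),
                   class = "hazard_profiles")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir, medium)
  res
}

#' @export
print.hazard_profiles <- function(x, ...) {
  cat("<hazard_profiles> ", nrow(x$profiles), " compounds, reference ",
      x$reference, "\n", sep = "")
  print(x$profiles, ...)
  invisible(x)
}

#' Bin Specificity Ratios for the summary heatmap
#'
#' The display bins used for the SR heatmap: `SR>100` (high specificity),
#' `SR>10` (medium), `1<SR<10` (moderate), `SR<1` (effects at cytotoxic
#' concentrations) and `no effect` for inactive endpoints.
#'
#' @param sr Specificity Ratios (`NA` = no effect).
#' @return Factor with the five bin levels.
#' @export
sr_bin <- function(sr) {
  lv <- c("SR>100", "SR>10", "1<SR<10", "SR<1", "no effect")
  out <- dplyr::case_when(
    is.na(sr) ~ "no effect",
    sr > 100 ~ "SR>100",
    sr > 10 ~ "SR>10",
    sr > 1 ~ "1<SR<10",
    TRUE ~ "SR<1"
  )
  factor(out, levels = lv)
}

#' Summary artifacts: SR heatmap matrix and two-axis scatter table
#'
#' @param result A [run_pipeline()] result.
#' @return List with `heatmap_sr` (compound x assay SR bins, wide),
#'   `heatmap_sr_score` (compound x assay SR-Scores, wide) and `scatter`
#'   (`compound_id`, `rep_ic10`, `cumulative_sr_score`, `category`).
#' @export
render_summary <- function(result) {
  stopifnot(inherits(result, "hazard_profiles"))
  ep <- result$endpoints
  ep$bin <- as.character(sr_bin(ep$sr))
  heat_bin <- tidyr::pivot_wider(
    ep[, c("compound_id", "assay_id", "bin")],
    names_from = "assay_id", values_from = "bin")
  heat_score <- tidyr::pivot_wider(
    ep[, c("compound_id", "assay_id", "sr_score")],
    names_from = "assay_id", values_from = "sr_score")
  scatter <- result$profiles[, c("compound_id", "rep_ic10",
                                 "cumulative_sr_score", "category")]
  list(heatmap_sr = heat_bin, heatmap_sr_score = heat_score,
       scatter = scatter)
}

#' Round a ratio the way the report prints it
#'
#' Ratios are reported to 2 significant figures, scores to 2 decimals.
#'
#' @param x Numeric vector.
#' @param what `"ratio"` or `"score"`.
#' @return Rounded numeric vector.
#' @export
report_round <- function(x, what = c("ratio", "score")) {
  what <- match.arg(what)
  if (what == "ratio") signif(x, 2) else round(x, 2)
}

write_pipeline_outputs <- function(res, out_dir, medium) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$profiles, file.path(out_dir, "profiles.csv"), na = "")
  readr::write_csv(res$endpoints, file.path(out_dir, "endpoints.csv"),
                   na = "")
  summ <- render_summary(res)
  readr::write_csv(summ$heatmap_sr, file.path(out_dir, "heatmap_sr.csv"),
                   na = "")
  readr::write_csv(summ$heatmap_sr_score,
                   file.path(out_dir, "heatmap_sr_score.csv"), na = "")
  readr::write_csv(summ$scatter, file.path(out_dir, "scatter.csv"), na = "")
  writeLines(res$log, file.path(out_dir, "pipeline_log.txt"))
  prov <- list(reference = res$reference,
               n_compounds = nrow(res$profiles),
               medium = unclass(medium),
               sr_basis = "median_ic10",
               package_version = as.character(utils::packageVersion("bpalt")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
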