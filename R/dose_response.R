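#' Remove concentrations at or above the cytotoxicity threshold
#'
#' Effect benchmarks (EC10, EC_IR1.5) must not be driven by responses at
#' cytotoxic concentrations, so only concentrations strictly below the IC10
#' are considered when fitting effect curves. A censored IC10 (`NA`, i.e.
#' "> highest tested concentration") leaves the data untouched.
#'
#' @param points A tibble of concentration-response points with at least a
#'   `concentration` column (mol/L).
#' @param ic10 Cytotoxicity IC10 in mol/L, or `NA` when censored.
#' @return The input rows with `concentration < ic10`, order preserved.
#' @export
mask_cytotoxic <- function(points, ic10) {
  stopifnot(is.data.frame(points), "concentration" %in% names(points))
  if (length(ic10) != 1L) stop("`ic10` must be a single value", call. = FALSE)
  if (is.na(ic10)) return(points)
  if (ic10 <= 0) stop("`ic10` must be > 0 or NA (censored)", call. = FALSE)
  points[points$concentration < ic10, , drop = FALSE]
}

#' Fit a concentration-response model
#'
#' The workhorse model is a three-parameter log-logistic with the bottom
#' fixed at 0,
#' \deqn{y = \frac{top}{1 + (EC_{50}/c)^{h}},}
#' fitted by Levenberg--Marquardt least squares in log10-concentration space.
#' Responses are expected on a scale where the reference compound's maximum
#' is 100 (effect assays), on the % inhibition scale (cytotoxicity; convert
#' viability with `100 - viability` before fitting), or as induction ratio
#' minus 1 for the oxidative-stress assay. The free top accommodates partial
#' agonists.
#'
#' `model = "linear_low_effect"` instead fits a zero-intercept straight line
#' through the low-effect region (responses `<= linear_max`), the
#' conventional evaluation for induction-ratio data, where `response` must
#' already be on the IR - 1 scale.
#'
#' @param points Tibble with columns `concentration` (mol/L, > 0) and
#'   `response`. Replicates are passed as additional rows.
#' @param model `"log_logistic"` (default) or `"linear_low_effect"`.
#' @param linear_max Upper response bound defining the low-effect region for
#'   the linear model (default 4, i.e. induction ratios up to 5).
#' @return An object of class `curve_fit`: a list with elements `model`,
#'   `top`, `ec50`, `hill`, `slope` (linear model), `se` (named), `vcov`,
#'   `converged`, `n_conc`, `cmax`.
#' @export
fit_curve <- function(points, model = c("log_logistic", "linear_low_effect"),
                      linear_max = 4) {
  model <- match.arg(model)
  stopifnot(is.data.frame(points),
            all(c("concentration", "response") %in% names(points)))
  if (any(points$concentration <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  cmax <- if (nrow(points)) max(points$concentration) else NA_real_
  if (model == "linear_low_effect") {
    return(fit_linear_low_effect(points, linear_max, cmax))
  }
  n_conc <- length(unique(points$concentration))
  if (n_conc < 4L) {
    stop("log-logistic fit needs >= 4 distinct concentrations after masking, ",
         "got ", n_conc, call. = FALSE)
  }
  lc <- log10(points$concentration)
  y <- points$response
  # crude starts: top from the high-concentration plateau, ec50 at half-max
  top0 <- max(stats::aggregate(y, list(lc), mean)$x)
  if (top0 <= 0) top0 <- max(y, 1)
  half <- top0 / 2
  ord <- order(lc)
  above <- which(y[ord] >= half)
  lec0 <- if (length(above)) lc[ord][above[1]] else stats::median(lc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ top / (1 + 10^(hill * (lec50 - lc))),
      start = list(top = top0, lec50 = lec0, hill = 1),
      lower = c(top = 1e-3, lec50 = min(lc) - 6, hill = 0.05),
      upper = c(top = Inf, lec50 = max(lc) + 6, hill = 15),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_curve_fit(model = "log_logistic", converged = FALSE,
                         n_conc = n_conc, cmax = cmax))
  }
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(0, 3, 3, dimnames = list(names(cf), names(cf)))
  })
  if (any(!is.finite(vc))) vc[!is.finite(vc)] <- 0
  se <- sqrt(pmax(diag(vc), 0))
  new_curve_fit(
    model = "log_logistic",
    top = unname(cf["top"]), ec50 = 10^unname(cf["lec50"]),
    hill = unname(cf["hill"]),
    se = c(top = unname(se["top"]), lec50 = unname(se["lec50"]),
           hill = unname(se["hill"])),
    vcov = vc, converged = TRUE, n_conc = n_conc, cmax = cmax
  )
}

fit_linear_low_effect <- function(points, linear_max, cmax) {
  pts <- points[points$response <= linear_max, , drop = FALSE]
  n_conc <- length(unique(pts$concentration))
  if (nrow(pts) < 2L) {
    stop("linear low-effect fit needs >= 2 points in the low-effect region",
         call. = FALSE)
  }
  fit <- stats::lm(response ~ 0 + concentration, data = pts)
  slope <- unname(stats::coef(fit)[1])
  # vcov warns on a zero-residual (noise-free) fit; the SE of 0 is correct
  vc <- suppressWarnings(stats::vcov(fit))
  se <- sqrt(diag(vc))[1]
  new_curve_fit(model = "linear_low_effect", slope = slope,
                se = c(slope = unname(se)),
                vcov = vc,
                converged = is.finite(slope), n_conc = n_conc, cmax = cmax)
}

new_curve_fit <- function(model, top = NA_real_, ec50 = NA_real_,
                          hill = NA_real_, slope = NA_real_,
                          se = c(top = NA_real_, lec50 = NA_real_,
                                 hill = NA_real_),
                          vcov = NULL, converged = FALSE, n_conc = 0L,
                          cmax = NA_real_) {
  structure(list(model = model, top = top, ec50 = ec50, hill = hill,
                 slope = slope, se = se, vcov = vcov, converged = converged,
                 n_conc = n_conc, cmax = cmax),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat("<curve_fit>", x$model,
      if (!x$converged) "(not converged)" else "", "\n")
  if (x$model == "log_logistic" && x$converged) {
    cat(sprintf("  top = %.4g  ec50 = %.4g M  hill = %.4g\n",
                x$top, x$ec50, x$hill))
  }
  if (x$model == "linear_low_effect" && x$converged) {
    cat(sprintf("  slope = %.4g per M\n", x$slope))
  }
  invisible(x)
}

#' Benchmark concentration from a fitted curve
#'
#' Inverts the fitted concentration-response model at a fixed absolute
#' response threshold: 10% of the reference compound's maximum for EC10
#' (i.e. y = 10 on the normalized scale, not 10% of the compound's own
#' maximum -- the distinction matters for partial agonists), 10% inhibition
#' for IC10, and an induction ratio of 1.5 (y = 0.5 on the IR - 1 scale) for
#' EC_IR1.5. For the log-logistic model the closed form is
#' \deqn{c = EC_{50} / (top/y - 1)^{1/h}.}
#' Standard errors come from first-order (delta-method) propagation of the
#' fit covariance.
#'
#' The benchmark is censored (`NA`, `active = FALSE`) when the fitted maximum
#' does not reach the threshold, when the fit did not converge, or when the
#' inverted concentration lies above the highest tested concentration.
#'
#' @param fit A [fit_curve()] result.
#' @param benchmark_type One of `"EC10"`, `"IC10"`, `"EC_IR1.5"`.
#' @param threshold Response threshold on the fitted scale. Defaults: 10 for
#'   EC10/IC10, 0.5 (IR - 1 scale) for EC_IR1.5.
#' @return A one-row tibble: `benchmark_type`, `benchmark` (mol/L, `NA` when
#'   censored), `se`, `censored`, `active`, `cmax`.
#' @export
benchmark_concentration <- function(fit,
                                    benchmark_type = c("EC10", "IC10",
                                                       "EC_IR1.5"),
                                    threshold = NULL) {
  benchmark_type <- match.arg(benchmark_type)
  stopifnot(inherits(fit, "curve_fit"))
  if (is.null(threshold)) {
    threshold <- if (benchmark_type == "EC_IR1.5") 0.5 else 10
  }
  censored_row <- function(active = FALSE) {
    tibble::tibble(benchmark_type = benchmark_type, benchmark = NA_real_,
                   se = NA_real_, censored = TRUE, active = active,
                   cmax = fit$cmax)
  }
  if (!fit$converged) return(censored_row())
  if (fit$model == "linear_low_effect") {
    if (!is.finite(fit$slope) || fit$slope <= 0) return(censored_row())
    bm <- threshold / fit$slope
    se <- threshold * fit$se[["slope"]] / fit$slope^2
  } else {
    if (fit$top <= threshold) return(censored_row())
    bm <- fit$ec50 / (fit$top / threshold - 1)^(1 / fit$hill)
    se <- delta_se_benchmark(fit, threshold)
  }
  if (is.finite(fit$cmax) && bm > fit$cmax) return(censored_row())
  tibble::tibble(benchmark_type = benchmark_type, benchmark = bm, se = se,
                 censored = FALSE, active = TRUE, cmax = fit$cmax)
}

# delta-method SE of the inverted log-logistic benchmark, numeric gradient
# in (top, lec50, hill)
delta_se_benchmark <- function(fit, threshold) {
  if (is.null(fit$vcov)) return(NA_real_)
  f <- function(p) {
    10^p[2] / (p[1] / threshold - 1)^(1 / p[3])
  }
  p0 <- c(fit$top, log10(fit$ec50), fit$hill)
  h <- pmax(abs(p0) * 1e-5, 1e-8)
  g <- vapply(1:3, function(i) {
    dp <- numeric(3); dp[i] <- h[i]
    (f(p0 + dp) - f(p0 - dp)) / (2 * h[i])
  }, numeric(1))
  v <- drop(t(g) %*% fit$vcov %*% g)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' Maximum efficacy as percent of the reference compound's maximum
#'
#' The fitted top of the log-logistic curve on the reference-normalized
#' scale; values below 100 indicate partial agonism.
#'
#' @param fit A converged log-logistic [fit_curve()] result.
#' @return Emax in % of reference maximum.
#' @export
emax_percent <- function(fit) {
  stopifnot(inherits(fit, "curve_fit"))
  if (fit$model != "log_logistic") {
    stop("Emax% is defined for the log-logistic model", call. = FALSE)
  }
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  fit$top
}

#' Median cytotoxicity IC10 across cell lines
#'
#' Censored IC10s (`NA`) are excluded; their count is reported via
#' `message()`. An all-censored input yields a censored (NA) median.
#'
#' @param ic10_per_cell_line Numeric vector of IC10 values in mol/L, `NA`
#'   for censored entries.
#' @return Median of the uncensored values, or `NA` if all are censored.
#' @export
median_ic10 <- function(ic10_per_cell_line) {
  n_cens <- sum(is.na(ic10_per_cell_line))
  if (n_cens > 0) {
    message(n_cens, " censored IC10 value(s) excluded from the median")
  }
  vals <- ic10_per_cell_line[!is.na(ic10_per_cell_line)]
  if (!length(vals)) return(NA_real_)
  stats::median(vals)
}

#' Fit all compound-by-assay curves in a tidy response table
#'
#' Convenience wrapper over [fit_curve()] and [benchmark_concentration()]
#' that, for every `compound_id` x `assay_id` combination, applies
#' cytotoxicity masking (when an IC10 lookup is supplied), fits the model
#' appropriate for the assay's `response_scale`, and returns one benchmark
#' row per curve.
#'
#' @param responses Tidy tibble with columns `compound_id`, `assay_id`,
#'   `concentration` (mol/L), `response`, `response_scale` (one of
#'   `"percent_effect"`, `"percent_inhibition"`, `"induction_ratio"`) and
#'   optionally `replicate`.
#' @param ic10_lookup Optional tibble `compound_id`, `ic10` (mol/L, `NA`
#'   censored) used for masking effect assays.
#' @param ir_model Model for induction-ratio assays: `"linear_low_effect"`
#'   (default, conventional) or `"log_logistic"`.
#' @return Tibble with one row per compound x assay: benchmark columns as in
#'   [benchmark_concentration()] plus `emax` (log-logistic fits only).
#' @export
fit_assay_table <- function(responses, ic10_lookup = NULL,
                            ir_model = c("linear_low_effect",
                                         "log_logistic")) {
  ir_model <- match.arg(ir_model)
  need <- c("compound_id", "assay_id", "concentration", "response",
            "response_scale")
  if (!all(need %in% names(responses))) {
    stop("`responses` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  groups <- dplyr::distinct(responses, .data$compound_id, .data$assay_id,
                            .data$response_scale)
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    pts <- dplyr::filter(responses, .data$compound_id == g$compound_id,
                         .data$assay_id == g$assay_id)
    scale <- g$response_scale
    if (scale != "percent_inhibition" && !is.null(ic10_lookup)) {
      ic <- ic10_lookup$ic10[match(g$compound_id, ic10_lookup$compound_id)]
      if (length(ic) == 1L && !is.na(ic)) pts <- mask_cytotoxic(pts, ic)
    }
    if (scale == "induction_ratio") {
      pts$response <- pts$response - 1
      model <- ir_model
      btype <- "EC_IR1.5"
    } else {
      model <- "log_logistic"
      btype <- if (scale == "percent_inhibition") "IC10" else "EC10"
    }
    fit <- tryCatch(fit_curve(pts, model = model), error = function(e) NULL)
    if (is.null(fit)) {
      bm <- tibble::tibble(benchmark_type = btype, benchmark = NA_real_,
                           se = NA_real_, censored = TRUE, active = FALSE,
                           cmax = if (nrow(pts)) max(pts$concentration)
                                  else NA_real_)
    } else {
      bm <- benchmark_concentration(fit, btype)
    }
    bm$emax <- if (!is.null(fit) && fit$model == "log_logistic" &&
                   fit$converged) fit$top else NA_real_
    dplyr::bind_cols(g[, c("compound_id", "assay_id")], bm)
  })
  dplyr::bind_rows(out)
}
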