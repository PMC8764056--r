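#' Standardize a numeric vector to mean 0, SD 1
#'
#' The tortuosity metrics have very different scales, so distribution shapes
#' are compared after bringing every metric to the same mean and standard
#' deviation (sample SD, denominator n - 1).
#'
#' @param values Numeric vector, at least 2 values with non-zero SD.
#' @return The standardized vector.
#' @export
standardize <- function(values) {
  if (length(values) < 2) {
    rlang::abort("standardize needs at least 2 values",
                 class = "tortuometry_degenerate_input")
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    rlang::abort("cannot standardize a constant vector (zero SD)",
                 class = "tortuometry_degenerate_input")
  }
  (values - mean(values)) / s
}

check_moment_input <- function(values, min_n) {
  if (length(values) < min_n || anyNA(values)) {
    rlang::abort(sprintf("need at least %d finite values", min_n),
                 class = "tortuometry_degenerate_input")
  }
  if (stats::sd(values) == 0) {
    rlang::abort("moments undefined for a constant vector",
                 class = "tortuometry_degenerate_input")
  }
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' Bias-corrected third standardized moment: 0 for a symmetric distribution,
#' positive for a right-skewed one.
#'
#' @param values Numeric vector (>= 3 values, non-zero SD).
#' @return Skewness scalar.
#' @export
sample_skewness <- function(values) {
  check_moment_input(values, 3)
  e1071::skewness(values, type = 2)
}

#' Excess kurtosis (bias-corrected)
#'
#' Fourth standardized moment minus 3, so a normal distribution scores 0;
#' positive values mean heavier tails than normal.
#'
#' @param values Numeric vector (>= 4 values, non-zero SD).
#' @return Excess kurtosis scalar.
#' @export
excess_kurtosis <- function(values) {
  check_moment_input(values, 4)
  e1071::kurtosis(values, type = 2)
}

#' Significance class of a p-value
#'
#' `"***"` for p <= 0.001, `"**"` for p <= 0.01, `"*"` for p <= 0.05,
#' `""` otherwise (boundaries inclusive).
#'
#' @param p p-value(s) in \[0, 1\]; vectorized.
#' @return Character vector of star strings.
#' @export
significance_class <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort("p-values must lie in [0, 1]", class = "tortuometry_invalid_input")
  }
  dplyr::case_when(p <= 0.001 ~ "***", p <= 0.01 ~ "**", p <= 0.05 ~ "*",
                   .default = "")
}

#' Ordinary least squares fit with adjusted R-squared
#'
#' Least-squares regression of a response on one or more predictors, the
#' workhorse of the tortuosity-vs-low-TAWSS correlation analysis. Reports
#' R^2, R^2 adjusted for the number of predictors
#' (1 - (1 - R^2)(n - 1)/(n - k - 1), which may go negative for models worse
#' than the mean-only fit), and the overall F-test p-value (for a single
#' predictor this equals the two-sided t-test of the slope).
#'
#' @param data A data frame.
#' @param response Name of the response column (string).
#' @param predictors Character vector of predictor column names.
#' @return A `tortuometry_ols` object; see [tidy.tortuometry_ols()] and
#'   [glance.tortuometry_ols()].
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' glance(ols_fit(d, "y", "x"))
#' @export
ols_fit <- function(data, response, predictors) {
  n <- nrow(data)
  k <- length(predictors)
  if (n <= k + 1) {
    rlang::abort(sprintf("need n > k + 1 observations (n = %d, k = %d)", n, k),
                 class = "tortuometry_insufficient_data")
  }
  f <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(f, data = data)
  if (fit$rank < k + 1) {
    rlang::abort("design matrix is rank-deficient (collinear predictors)",
                 class = "tortuometry_collinearity_error")
  }
  sm <- summary(fit)
  p <- if (k == 0) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE)
  structure(list(fit = fit, response = response, predictors = predictors,
                 n = n, k = k,
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 sigma = sm$sigma,
                 p_value = unname(p), stars = significance_class(unname(p))),
            class = "tortuometry_ols")
}

#' @export
print.tortuometry_ols <- function(x, ...) {
  cat(sprintf("<ols: %s ~ %s | n = %d, R2 = %.3f, adj R2 = %.3f, p = %.3g %s>\n",
              x$response, paste(x$predictors, collapse = " + "),
              x$n, x$r2, x$adj_r2, x$p_value, x$stars))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of an OLS fit
#'
#' @param x A `tortuometry_ols` object.
#' @param conf.level Confidence level for the slope intervals.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.tortuometry_ols <- function(x, conf.level = 0.95, ...) {
  ct <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit, level = conf.level)
  tibble::tibble(term = rownames(ct), estimate = ct[, 1], std.error = ct[, 2],
                 statistic = ct[, 3], p.value = ct[, 4],
                 conf.low = ci[, 1], conf.high = ci[, 2])
}

#' One-row model summary of an OLS fit
#'
#' @param x A `tortuometry_ols` object.
#' @param ... Unused.
#' @return A tibble with `r2`, `adj_r2`, `sigma`, `p_value`, `stars`, `n`, `k`.
#' @export
glance.tortuometry_ols <- function(x, ...) {
  tibble::tibble(r2 = x$r2, adj_r2 = x$adj_r2, sigma = x$sigma,
                 p_value = x$p_value, stars = x$stars, n = x$n, k = x$k)
}

branch_levels <- function() c("LMCA", "LAD", "LCx")

#' Aggregate per-branch cohort rows to whole-bifurcation rows
#'
#' Length-weighted mean of each metric over a case's branches, and the
#' whole-surface low-TAWSS fraction: the `whole_fraction` column when the
#' cohort table carries one (e.g. measured on the full mesh), otherwise the
#' area-proxy length-weighted mean of the branch fractions.
#'
#' @param cohort A per-branch cohort tibble (see [generate_cohort()]).
#' @return A per-case tibble with `branch = "bifurcation"`.
#' @export
aggregate_bifurcation <- function(cohort) {
  metrics <- intersect(c(primary_metrics(), "kappa_ta", "kappa_tr"), names(cohort))
  w <- if ("L" %in% names(cohort)) cohort$L else rep(1, nrow(cohort))
  cohort$.w <- w
  out <- cohort |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metrics),
                    ~ stats::weighted.mean(.x, w = .data$.w)),
      low_tawss_fraction = if ("whole_fraction" %in% names(cohort))
        .data$whole_fraction[1]
      else stats::weighted.mean(.data$low_tawss_fraction, w = .data$.w),
      .groups = "drop") |>
    dplyr::mutate(branch = "bifurcation", .after = "case_id")
  out
}

#' Cohort-level tortuosity vs low-TAWSS regression grid
#'
#' For each primary tortuosity metric and each segment (LMCA, LAD, LCx and
#' the complete bifurcation), regresses the low-TAWSS area fraction on the
#' metric and reports the adjusted R^2, overall p-value and significance
#' stars — a 4 x 4 results grid.
#'
#' @param cohort Per-branch cohort tibble with columns `case_id`, `branch`,
#'   the metric columns, and `low_tawss_fraction` (optionally
#'   `whole_fraction` and `L`).
#' @param metrics Metric columns to analyse (default [primary_metrics()]).
#' @return A `tortuometry_cohort_analysis` tibble: `metric`, `segment`,
#'   `slope`, `intercept`, `r2`, `adj_r2`, `p_value`, `stars`, `n`.
#' @export
run_cohort_analysis <- function(cohort, metrics = primary_metrics()) {
  if (!all(c("case_id", "branch", "low_tawss_fraction") %in% names(cohort))) {
    rlang::abort("cohort needs case_id, branch and low_tawss_fraction columns",
                 class = "tortuometry_invalid_input")
  }
  if (anyDuplicated(cohort[, c("case_id", "branch")])) {
    rlang::abort("duplicated (case_id, branch) rows in cohort table",
                 class = "tortuometry_invalid_input")
  }
  missing_m <- setdiff(metrics, names(cohort))
  if (length(missing_m)) {
    rlang::abort(paste("cohort table lacks metric columns:",
                       paste(missing_m, collapse = ", ")),
                 class = "tortuometry_invalid_input")
  }
  branches <- intersect(branch_levels(), unique(cohort$branch))
  if (length(branches) == 0) {
    rlang::abort("cohort has no recognizable branch labels (LMCA/LAD/LCx)",
                 class = "tortuometry_invalid_input")
  }
  segments <- c(purrr::map(branches, ~ dplyr::filter(cohort, .data$branch == .x)) |>
                  rlang::set_names(branches),
                list(bifurcation = aggregate_bifurcation(cohort)))
  grid <- tidyr::expand_grid(metric = metrics, segment = names(segments))
  out <- purrr::pmap(grid, function(metric, segment) {
    d <- segments[[segment]]
    fit <- ols_fit(d, "low_tawss_fraction", metric)
    co <- stats::coef(fit$fit)
    tibble::tibble(metric = metric, segment = segment,
                   slope = unname(co[2]), intercept = unname(co[1]),
                   r2 = fit$r2, adj_r2 = fit$adj_r2,
                   p_value = fit$p_value, stars = fit$stars, n = fit$n)
  }) |> dplyr::bind_rows()
  class(out) <- c("tortuometry_cohort_analysis", class(out))
  out
}

#' Distribution shape of the tortuosity metrics across a cohort
#'
#' Excess kurtosis and skewness of each metric per segment (branches plus
#' the whole bifurcation), the diagnostics used to judge how far each
#' metric's cohort distribution sits from normality.
#'
#' @inheritParams run_cohort_analysis
#' @return A tibble: `metric`, `segment`, `kurtosis`, `skewness`.
#' @export
distribution_shape <- function(cohort, metrics = primary_metrics()) {
  branches <- intersect(branch_levels(), unique(cohort$branch))
  segs <- c(purrr::map(branches, ~ dplyr::filter(cohort, .data$branch == .x)) |>
              rlang::set_names(branches),
            list(bifurcation = aggregate_bifurcation(cohort)))
  tidyr::expand_grid(metric = metrics, segment = names(segs)) |>
    purrr::pmap(function(metric, segment) {
      v <- segs[[segment]][[metric]]
      tibble::tibble(metric = metric, segment = segment,
                     kurtosis = excess_kurtosis(v), skewness = sample_skewness(v))
    }) |> dplyr::bind_rows()
}

#' Human-readable report of a cohort analysis grid
#'
#' Formats the metric x segment grid as a text table with adjusted R^2,
#' p-values and star annotations.
#'
#' @param analysis Result of [run_cohort_analysis()].
#' @return Character vector of report lines (invisibly printed with `cat`).
#' @export
format_cohort_report <- function(analysis) {
  wide <- analysis |>
    dplyr::mutate(cell = sprintf("%6.3f %s%s", .data$adj_r2,
                                 format_p(.data$p_value), .data$stars)) |>
    dplyr::select("metric", "segment", "cell") |>
    tidyr::pivot_wider(names_from = "segment", values_from = "cell")
  header <- sprintf("%-10s %s", "metric",
                    paste(sprintf("%-22s", names(wide)[-1]), collapse = " "))
  rows <- purrr::pmap_chr(wide, function(metric, ...) {
    sprintf("%-10s %s", metric,
            paste(sprintf("%-22s", c(...)), collapse = " "))
  })
  c("adjusted R2 (p-value) of low-TAWSS area fraction ~ metric",
    header, rows)
}

format_p <- function(p) {
  ifelse(p < 0.001, "(<0.001)", sprintf("(%.3f)", p))
}
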