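#' Plot a centerline's coordinate-plane projections
#'
#' Shows the 3D path as its xy, xz and yz projections, the quickest visual
#' check that a centerline is ordered and smooth.
#'
#' @param centerlines A centerline or list of centerlines.
#' @return A ggplot object.
#' @export
plot_centerline <- function(centerlines) {
  cls <- as_centerline_list(centerlines)
  d <- purrr::imap(cls, ~ dplyr::mutate(tibble::as_tibble(.x), branch = .y)) |>
    dplyr::bind_rows()
  long <- dplyr::bind_rows(
    dplyr::transmute(d, u = .data$x, v = .data$y, plane = "xy", branch = .data$branch),
    dplyr::transmute(d, u = .data$x, v = .data$z, plane = "xz", branch = .data$branch),
    dplyr::transmute(d, u = .data$y, v = .data$z, plane = "yz", branch = .data$branch))
  ggplot2::ggplot(long, ggplot2::aes(.data$u, .data$v, colour = .data$branch)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~plane, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "mm", colour = "branch") +
    ggplot2::theme_minimal()
}

#' Plot a curvature profile along arc length
#'
#' @param p A curvature profile (optionally with `dkappa_ds`).
#' @return A ggplot object.
#' @export
plot_curvature_profile <- function(p) {
  d <- tibble::as_tibble(p) |>
    tidyr::pivot_longer(-"s", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(kappa = "kappa (mm^-1)", dkappa_ds = "dkappa/ds (mm^-2)"))) +
    ggplot2::labs(x = "arc length s (mm)", y = NULL,
                  title = attr(p, "label", exact = TRUE)) +
    ggplot2::theme_minimal()
}

#' Standardized metric distributions across a cohort
#'
#' Density of each tortuosity metric after standardization to mean 0 / SD 1,
#' so distribution shapes (skew, tail weight) are directly comparable.
#'
#' @param cohort Per-branch cohort tibble.
#' @param metrics Metric columns (default [primary_metrics()]).
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(cohort, metrics = primary_metrics()) {
  d <- cohort |>
    dplyr::select(dplyr::all_of(metrics)) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), standardize)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(.data$value, colour = .data$metric)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "standardized value", y = "density",
                  title = "Standardized tortuosity metric distributions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort analysis grid
#'
#' Adjusted R-squared per metric and segment, annotated with significance
#' stars; negative bars mark models worse than the mean-only fit.
#'
#' @param object A `tortuometry_cohort_analysis` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tortuometry_cohort_analysis <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$segment, .data$adj_r2, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars),
                       position = ggplot2::position_dodge(width = 0.9),
                       vjust = -0.3, size = 5) +
    ggplot2::labs(x = NULL, y = "adjusted R2",
                  title = "Low-TAWSS area fraction explained per tortuosity metric") +
    ggplot2::theme_minimal()
}
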