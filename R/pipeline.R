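#' Run configuration for the analysis pipeline
#'
#' Bundles the geometric and hemodynamic parameters every stage logs:
#' resampling spacing (0.01 mm), optional smoothing width, branch analysis
#' length (10 mm from the bifurcation), and the low-TAWSS threshold
#' (0.4 Pa).
#'
#' @param spacing Resampling spacing, mm (> 0).
#' @param smooth_sigma Centerline smoothing width, mm (>= 0; 0 = off).
#' @param branch_length Branch truncation length from the bifurcation, mm.
#' @param tawss_threshold Low-TAWSS threshold, Pa.
#' @param tawss_array,mask_array Array names in surface files.
#' @param seed Integer seed for any stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(spacing = 0.01, smooth_sigma = 0, branch_length = 10,
                       tawss_threshold = 0.4, tawss_array = "TAWSS",
                       mask_array = "region", seed = 1L) {
  stopifnot(spacing > 0, smooth_sigma >= 0, branch_length > 0,
            tawss_threshold > 0)
  structure(list(spacing = spacing, smooth_sigma = smooth_sigma,
                 branch_length = branch_length,
                 tawss_threshold = tawss_threshold,
                 tawss_array = tawss_array, mask_array = mask_array,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Per-branch tortuosity metrics for a set of centerline files
#'
#' Reads each file, truncates every branch to `branch_length` from its
#' proximal end, and computes the full metric set under `config`.
#'
#' @param paths Centerline files (CSV/VTK/VTP); one case per file.
#' @param config A [run_config()].
#' @return Tibble of metrics, one row per (case, branch); short branches
#'   carry `short_branch = TRUE`.
#' @export
metrics_from_files <- function(paths, config = run_config()) {
  purrr::map(paths, function(p) {
    cls <- read_centerline(p)
    case <- sub("\\.[^.]+$", "", basename(p))
    rows <- purrr::imap(cls, function(cl, nm) {
      clr <- resample_centerline(cl, config$spacing)
      clt <- truncate_branch(clr, length = config$branch_length)
      m <- compute_tortuosity(clt, spacing = config$spacing,
                              sigma = config$smooth_sigma, resample = FALSE)
      m$branch <- nm
      m$short_branch <- isTRUE(attr(clt, "short_branch"))
      m
    })
    dplyr::bind_rows(rows) |> dplyr::mutate(case_id = case, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Low-TAWSS area fractions for a set of surface files
#'
#' @param paths Surface files (.vtk/.vtp), one per (case, branch) or case.
#' @param config A [run_config()].
#' @return Tibble with `case_id` and `low_tawss_fraction`.
#' @export
tawss_from_files <- function(paths, config = run_config()) {
  purrr::map(paths, function(p) {
    s <- read_surface_field(p, tawss_array = config$tawss_array,
                            mask_array = config$mask_array)
    tibble::tibble(case_id = sub("\\.[^.]+$", "", basename(p)),
                   low_tawss_fraction =
                     low_tawss_area_fraction(s, threshold = config$tawss_threshold))
  }) |> dplyr::bind_rows()
}

#' Run the full cohort analysis on a cohort table
#'
#' Convenience wrapper: regression grid, distribution shape, and the
#' formatted report in one object.
#'
#' @param cohort Per-branch cohort tibble (see [run_cohort_analysis()]).
#' @param metrics Metric columns to analyse.
#' @return A list: `analysis` (regression grid), `shape`
#'   (kurtosis/skewness), `report` (text lines).
#' @export
cohort_report <- function(cohort, metrics = primary_metrics()) {
  analysis <- run_cohort_analysis(cohort, metrics = metrics)
  list(analysis = analysis,
       shape = distribution_shape(cohort, metrics = metrics),
       report = format_cohort_report(analysis))
}
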