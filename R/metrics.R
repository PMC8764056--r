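#' Tortuosity index: vessel length over chord length
#'
#' tau = L / C, the classic clinical tortuosity measure: the ratio of the
#' centerline arc length to the straight-line distance between its endpoints.
#' Always >= 1; 1 for a straight vessel. It sees only the endpoints of the
#' path, which is exactly why it can disagree with curvature-based measures.
#'
#' @param c A centerline.
#' @return tau (dimensionless).
#' @export
tortuosity_index <- function(c) {
  L <- arc_length(c)
  C <- chord_length(c)
  if (C == 0) {
    rlang::abort("tortuosity index is undefined for a closed curve (chord = 0)",
                 class = "tortuometry_undefined_metric")
  }
  if (C < 0.01 * L) {
    rlang::warn("chord is < 1% of vessel length; tortuosity index is near-divergent")
  }
  L / C
}

#' Total absolute-curvature
#'
#' Integral of kappa over arc length: the total turning angle of the curve in
#' radians. Length-dependent (a long gently-curved vessel can out-score a
#' short kinked one), which is why cohort analyses prefer the per-length
#' average; it is retained here because its invariance under uniform scaling
#' anchors the metric transformation laws.
#'
#' @param p A curvature profile.
#' @return kappa_ta (radians, dimensionless).
#' @export
total_absolute_curvature <- function(p) {
  trapz_s(p$s, p$kappa)
}

#' Total squared-curvature
#'
#' Integral of kappa^2 over arc length (mm^-1). Like the total
#' absolute-curvature it grows with vessel length and is excluded from
#' cohort correlation by default.
#'
#' @param p A curvature profile.
#' @return kappa_tr (mm^-1).
#' @export
total_squared_curvature <- function(p) {
  trapz_s(p$s, p$kappa^2)
}

profile_length <- function(p) {
  L <- p$s[nrow(p)] - p$s[1]
  if (L <= 0) {
    rlang::abort("curvature profile spans zero length",
                 class = "tortuometry_undefined_metric")
  }
  L
}

#' Average absolute-curvature
#'
#' Total absolute-curvature divided by vessel length L: the mean bending per
#' unit length (mm^-1), the curvature measure that tracks low-TAWSS burden
#' most closely in left main bifurcations.
#'
#' @param p A curvature profile.
#' @return kappa_a (mm^-1).
#' @export
average_absolute_curvature <- function(p) {
  total_absolute_curvature(p) / profile_length(p)
}

#' RMS-curvature
#'
#' Square root of the per-length average of kappa^2 (mm^-1); penalizes sharp
#' bends more than the plain average. Always >= the average
#' absolute-curvature (power-mean inequality), with equality only for
#' constant curvature.
#'
#' @param p A curvature profile.
#' @return kappa_r (mm^-1).
#' @export
rms_curvature <- function(p) {
  sqrt(total_squared_curvature(p) / profile_length(p))
}

#' Average squared-derivative-curvature
#'
#' Per-length integral of (dkappa/ds)^2 (mm^-4); sensitive to rapid changes
#' in curvature rather than curvature itself, so any constant-curvature curve
#' (line, circle, helix) scores 0.
#'
#' @param p A curvature profile with `dkappa_ds` (see [curvature_derivative()]).
#' @return kappa_d (mm^-4).
#' @export
average_squared_derivative_curvature <- function(p) {
  if (!("dkappa_ds" %in% names(p))) {
    rlang::abort("profile has no dkappa_ds; call curvature_derivative() first",
                 class = "tortuometry_precondition_error")
  }
  trapz_s(p$s, p$dkappa_ds^2) / profile_length(p)
}

#' Units of the tortuosity metrics
#'
#' @return A named character vector mapping metric column names to units.
#' @export
metric_units <- function() {
  c(tau = "dimensionless", kappa_ta = "rad", kappa_tr = "mm^-1",
    kappa_a = "mm^-1", kappa_r = "mm^-1", kappa_d = "mm^-4",
    L = "mm", C = "mm")
}

#' Names of the four primary tortuosity metrics
#'
#' The per-length measures used in cohort correlation (the two `total`
#' measures are length-dependent and excluded by default).
#' @return Character vector `c("tau", "kappa_a", "kappa_r", "kappa_d")`.
#' @export
primary_metrics <- function() c("tau", "kappa_a", "kappa_r", "kappa_d")

#' Compute the full tortuosity metric set for one vessel segment
#'
#' Runs the standard pipeline: uniform resampling, optional Gaussian
#' smoothing, curvature and curvature-derivative profiles, then all six
#' tortuosity measures plus L and C.
#'
#' @param c A centerline.
#' @param spacing Resampling spacing in mm (default 0.01).
#' @param sigma Smoothing kernel width in mm (default 0 = off).
#' @param resample Set `FALSE` if `c` is already uniformly sampled at
#'   `spacing` (skips the spline pass).
#' @return A one-row tibble: `branch`, `tau`, `kappa_ta`, `kappa_tr`,
#'   `kappa_a`, `kappa_r`, `kappa_d`, `L`, `C`, `spacing`, `sigma`. Units per
#'   [metric_units()].
#' @examples
#' compute_tortuosity(make_analytic_curve("helix", a = 2, b = 1, turns = 2))
#' @export
compute_tortuosity <- function(c, spacing = 0.01, sigma = 0, resample = TRUE) {
  cl <- if (resample) resample_centerline(c, spacing) else c
  if (sigma > 0) cl <- smooth_centerline(cl, sigma)
  p <- curvature_derivative(curvature_profile(cl))
  tibble::new_tibble(list(
    branch = branch_label(cl),
    tau = tortuosity_index(cl),
    kappa_ta = total_absolute_curvature(p),
    kappa_tr = total_squared_curvature(p),
    kappa_a = average_absolute_curvature(p),
    kappa_r = rms_curvature(p),
    kappa_d = average_squared_derivative_curvature(p),
    L = arc_length(cl),
    C = chord_length(cl),
    spacing = spacing,
    sigma = sigma), nrow = 1L)
}

#' Tortuosity metrics for a set of branches
#'
#' Maps [compute_tortuosity()] over a named list of centerlines (e.g. the
#' LMCA/LAD/LCx branches of one bifurcation) and binds the rows.
#'
#' @param branches A list of centerlines; names override branch labels.
#' @param case_id Optional case identifier column value.
#' @inheritParams compute_tortuosity
#' @return A tibble with one row per branch.
#' @export
compute_tortuosity_set <- function(branches, case_id = NULL, spacing = 0.01,
                                   sigma = 0, resample = TRUE) {
  rows <- purrr::imap(branches, function(cl, nm) {
    r <- compute_tortuosity(cl, spacing = spacing, sigma = sigma, resample = resample)
    if (is.character(nm) && nzchar(nm)) r$branch <- nm
    r
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(case_id)) out <- dplyr::mutate(out, case_id = case_id, .before = 1)
  out
}
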