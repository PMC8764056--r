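#' Curvature profile of a uniformly resampled centerline
#'
#' Curvature is the reciprocal of the osculating-circle radius at each point
#' of the centerline, computed as kappa = |r' x r''| / |r'|^3 with the curve
#' parameterized by arc length. Derivatives use second-order central finite
#' differences on the uniform grid, one-sided second-order stencils at the
#' endpoints, and exact non-uniform stencils over the (possibly shorter)
#' final interval left by endpoint retention. Values below 1e-12 are clamped
#' to 0 so that |kappa| carries no sign noise.
#'
#' Mild spacing jitter (e.g. segmentation noise on a nominally uniform
#' centerline) is tolerated and treated as a uniform grid at the mean
#' spacing; grossly irregular polylines are refused.
#'
#' @param c A uniformly resampled centerline with at least 5 points.
#' @return A `tortuometry_curvature_profile` tibble with columns `s` (arc
#'   length, mm) and `kappa` (mm^-1, >= 0); attributes `spacing` and `label`.
#' @examples
#' helix <- make_analytic_curve("helix", a = 2, b = 1, turns = 1)
#' cp <- curvature_profile(helix)
#' mean(cp$kappa)  # a / (a^2 + b^2) = 0.4
#' @export
curvature_profile <- function(c) {
  if (nrow(c) < 5) {
    rlang::abort("curvature needs at least 5 points",
                 class = "tortuometry_invalid_input")
  }
  m <- as_xyz_matrix(c)
  seg <- row_norms3(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
  h <- nominal_spacing(seg)
  kappa <- kappa_core(m, h, seg = seg)
  n <- length(kappa)
  s <- h * (seq_len(n) - 1)
  # keep the true position of the retained endpoint so integrals cover the
  # full arc length
  if (trailing_differs(seg, h)) s[n] <- s[n - 1] + seg[n - 1]
  out <- tibble::new_tibble(list(s = s, kappa = kappa), nrow = n)
  attr(out, "spacing") <- h
  attr(out, "label") <- branch_label(c)
  class(out) <- c("tortuometry_curvature_profile", class(out))
  out
}

# nominal grid spacing of a segment-length vector. Zero-mean jitter around a
# uniform grid is fine (block means stay on the nominal value); structural
# non-uniformity (unresampled polylines) is refused.
nominal_spacing <- function(seg) {
  body <- if (length(seg) > 2) seg[-length(seg)] else seg
  if (length(body) < 25) {
    h <- stats::median(body)
    ok <- max(abs(body - h)) <= 0.5 * h
  } else {
    blocks <- vapply(split(body, ceiling(seq_along(body) / 25)), mean, numeric(1))
    h <- stats::median(blocks)
    ok <- max(abs(blocks - h)) <= 0.5 * h
  }
  if (!ok) {
    rlang::abort("centerline is not (nominally) uniformly spaced; call resample_centerline() first",
                 class = "tortuometry_precondition_error")
  }
  mean(body)
}

body_is_uniform <- function(seg, h) {
  max(abs(seg[-length(seg)] - h)) <= 1e-3 * h
}

trailing_differs <- function(seg, h) {
  body_is_uniform(seg, h) && abs(seg[length(seg)] - h) > 1e-3 * h
}

# finite-difference weights for the d-th derivative at offset nodes `delta`
# (solves the Vandermonde moment conditions; used only at trailing points)
deriv_weights <- function(delta, d) {
  k <- length(delta)
  A <- t(vapply(0:(k - 1), function(p) delta^p / factorial(p), numeric(k)))
  solve(A, as.numeric(0:(k - 1) == d))
}

# kappa = |r' x r''| / |r'|^3 (matrix hot path). On an exactly uniform body
# with a short retained final interval, the last two points get exact
# non-uniform stencils; jittered grids are treated as uniform at h.
kappa_core <- function(m, h, seg = NULL) {
  n <- nrow(m)
  if (is.null(seg)) {
    seg <- row_norms3(m[-1, , drop = FALSE] - m[-n, , drop = FALSE])
  }
  d1 <- fd_first(m, h)
  d2 <- fd_second(m, h)
  if (trailing_differs(seg, h)) {
    hl <- seg[length(seg)]
    idx <- (n - 3):n
    s_tail <- c(-2 * h - hl, -h - hl, -hl, 0)
    for (row in c(n - 1L, n)) {
      delta <- s_tail - s_tail[row - n + 4L]
      d1[row, ] <- deriv_weights(delta, 1) %*% m[idx, , drop = FALSE]
      d2[row, ] <- deriv_weights(delta, 2) %*% m[idx, , drop = FALSE]
    }
  }
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  kappa <- row_norms3(cr) / row_norms3(d1)^3
  kappa[kappa < 1e-12] <- 0
  if (any(!is.finite(kappa))) {
    rlang::abort("curvature is not finite; check for duplicate points",
                 class = "tortuometry_invalid_input")
  }
  kappa
}

# second-order finite differences of the rows of a matrix (or a vector)
# sampled on a uniform grid of step h
fd_first <- function(m, h) {
  vec <- is.null(dim(m))
  if (vec) m <- matrix(m, ncol = 1)
  n <- nrow(m)
  d <- (m[c(2:n, n), , drop = FALSE] - m[c(1, 1:(n - 1)), , drop = FALSE]) / (2 * h)
  d[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / (2 * h)
  d[n, ] <- (3 * m[n, ] - 4 * m[n - 1, ] + m[n - 2, ]) / (2 * h)
  if (vec) d[, 1] else d
}

fd_second <- function(m, h) {
  vec <- is.null(dim(m))
  if (vec) m <- matrix(m, ncol = 1)
  n <- nrow(m)
  d <- (m[c(2:n, n), , drop = FALSE] - 2 * m + m[c(1, 1:(n - 1)), , drop = FALSE]) / h^2
  d[1, ] <- (2 * m[1, ] - 5 * m[2, ] + 4 * m[3, ] - m[4, ]) / h^2
  d[n, ] <- (2 * m[n, ] - 5 * m[n - 1, ] + 4 * m[n - 2, ] - m[n - 3, ]) / h^2
  if (vec) d[, 1] else d
}

#' Add the curvature derivative dkappa/ds to a profile
#'
#' Central finite differences of kappa over arc length (one-sided at the
#' endpoints, non-uniform stencils over a short trailing interval), feeding
#' the average squared-derivative-curvature metric.
#'
#' @param p A curvature profile from [curvature_profile()].
#' @return The profile with a `dkappa_ds` column (mm^-2).
#' @export
curvature_derivative <- function(p) {
  h <- profile_spacing(p)
  n <- nrow(p)
  d <- fd_first(p$kappa, h)
  hl <- p$s[n] - p$s[n - 1]
  if (abs(hl - h) > 1e-3 * h) {
    idx <- (n - 3):n
    s_tail <- p$s[idx]
    for (row in c(n - 1L, n)) {
      d[row] <- sum(deriv_weights(s_tail - p$s[row], 1) * p$kappa[idx])
    }
  }
  p$dkappa_ds <- d
  p
}

profile_spacing <- function(p) {
  h <- attr(p, "spacing", exact = TRUE)
  if (is.null(h)) {
    dh <- diff(p$s)
    body <- if (length(dh) > 2) dh[-length(dh)] else dh
    if (max(abs(body - body[1])) > 1e-6 * body[1]) {
      rlang::abort("curvature profile is not uniformly spaced",
                   class = "tortuometry_precondition_error")
    }
    h <- body[1]
  }
  h
}

#' Trapezoidal integral of a uniformly sampled function
#'
#' Realizes the arc-length integrals in the curvature-based tortuosity
#' measures; endpoint samples get the usual half weights.
#'
#' @param values Sampled function values (>= 2 samples).
#' @param spacing Uniform sample spacing.
#' @return The integral as a scalar.
#' @export
integrate_profile <- function(values, spacing) {
  if (length(values) < 2) {
    rlang::abort("integrate_profile needs at least 2 samples",
                 class = "tortuometry_invalid_input")
  }
  spacing * (sum(values) - (values[1] + values[length(values)]) / 2)
}

# trapezoid over the profile's own (possibly trailing-short) arc grid
trapz_s <- function(s, v) {
  n <- length(v)
  sum(diff(s) * (v[-1] + v[-n])) / 2
}
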