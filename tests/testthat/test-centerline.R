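test_that("arc length and chord length match closed forms", {
  seg <- centerline(data.frame(x = c(0, 3), y = c(0, 4), z = 0))
  expect_equal(arc_length(seg), 5)
  expect_equal(chord_length(seg), 5)

  semi <- make_analytic_curve("arc", radius = 1, angle = pi)
  expect_equal(arc_length(semi), pi, tolerance = 1e-4 / pi)
  expect_equal(chord_length(semi), 2, tolerance = 1e-6)

  # open traversal of a unit square: three edges
  sq <- centerline(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0))
  expect_equal(arc_length(sq), 3)

  # closed curve: coincident endpoints give zero chord
  closed <- centerline(data.frame(x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 1e-14), z = 0))
  expect_lt(chord_length(closed), 1e-12)

  expect_error(centerline(data.frame(x = 1, y = 1, z = 1)),
               class = "tortuometry_invalid_input")
  expect_error(centerline(data.frame(x = c(0, 0), y = c(1, 1), z = c(2, 2))),
               class = "tortuometry_invalid_input")
})

test_that("uniform resampling places points at equal arc steps", {
  seg <- centerline(data.frame(x = c(0, 1), y = 0, z = 0))
  r <- resample_centerline(seg, 0.01)
  expect_equal(nrow(r), 101)
  expect_equal(r$x, seq(0, 1, by = 0.01), tolerance = 1e-9)

  # idempotence on already-uniform input
  helix <- make_analytic_curve("helix", a = 2, b = 1, turns = 1, spacing = 0.05)
  r2 <- resample_centerline(helix, 0.05)
  expect_equal(nrow(r2), nrow(helix))
  disp <- sqrt(rowSums((as_matrix_xyz(r2) - as_matrix_xyz(helix))^2))
  expect_lt(max(disp), 0.05 / 10)

  # coarse 5-point quarter circle: spline recovers the analytic arc length
  th <- seq(0, pi / 2, length.out = 5)
  qc <- centerline(data.frame(x = cos(th), y = sin(th), z = 0))
  rq <- resample_centerline(qc, 0.01)
  expect_equal(arc_length(rq), pi / 2, tolerance = 0.005)

  expect_error(resample_centerline(seg, -1), class = "tortuometry_parameter_error")
  expect_error(resample_centerline(seg, 2), class = "tortuometry_parameter_error")
})

test_that("resampled length converges as spacing shrinks", {
  th <- seq(0, pi, length.out = 40)
  semi <- centerline(data.frame(x = cos(th), y = sin(th), z = 0))
  L1 <- arc_length(resample_centerline(semi, 0.02))
  L2 <- arc_length(resample_centerline(semi, 0.01))
  expect_lt(abs(L2 - L1) / L2, 0.001)
  expect_lte(chord_length(semi), arc_length(semi))
})

test_that("Gaussian smoothing fixes straight lines and damps noise", {
  seg <- resample_centerline(centerline(data.frame(x = c(0, 0, 10), y = c(0, 5, 10),
                                                   z = c(0, 2, 3))), 0.05)
  expect_identical(smooth_centerline(seg, 0), seg)

  line <- make_analytic_curve("line", length = 10, spacing = 0.05)
  sm <- smooth_centerline(line, 0.3)
  expect_equal(as_matrix_xyz(sm), as_matrix_xyz(line), tolerance = 1e-12)

  # noisy sine: smoothing pulls kappa_a back toward the noise-free value
  sine <- make_analytic_curve("planar_sine", amplitude = 0.5, wavelength = 2 * pi,
                              span = 2 * pi, spacing = 0.01)
  k_true <- average_absolute_curvature(curvature_profile(sine))
  noisy <- add_noise(sine, sd = 0.005, seed = 99)
  k_noisy <- average_absolute_curvature(curvature_profile(noisy))
  k_sm <- average_absolute_curvature(curvature_profile(smooth_centerline(noisy, 0.1)))
  expect_lt(abs(k_sm - k_true), abs(k_noisy - k_true))

  # smoothing never increases total absolute curvature of a noisy straight line
  nl <- add_noise(make_analytic_curve("line", length = 10, spacing = 0.01),
                  sd = 0.003, seed = 7)
  kta_raw <- total_absolute_curvature(curvature_profile(nl))
  kta_sm <- total_absolute_curvature(curvature_profile(smooth_centerline(nl, 0.2)))
  expect_lte(kta_sm, kta_raw)

  irregular <- centerline(data.frame(x = c(0, 1, 5, 10), y = 0, z = 0))
  expect_error(smooth_centerline(irregular, 0.1),
               class = "tortuometry_precondition_error")
})

test_that("branch truncation keeps the requested arc length", {
  long <- make_analytic_curve("line", length = 20, spacing = 0.01)
  tr <- truncate_branch(long, length = 10)
  expect_equal(arc_length(tr), 10, tolerance = 1e-9)
  expect_false(attr(tr, "short_branch"))

  short <- make_analytic_curve("line", length = 8, spacing = 0.01)
  tr2 <- truncate_branch(short, length = 10)
  expect_equal(arc_length(tr2), 8, tolerance = 1e-9)
  expect_true(attr(tr2, "short_branch"))

  helix <- make_analytic_curve("helix", a = 2, b = 1, turns = 2, spacing = 0.01)
  tr3 <- truncate_branch(helix, length = 10)
  expect_equal(arc_length(tr3), 10, tolerance = 0.01)

  expect_error(truncate_branch(long, length = 10, origin = c(5, 5, 5)),
               class = "tortuometry_invalid_input")
  expect_silent(truncate_branch(long, length = 10, origin = c(0, 0, 0)))
})
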