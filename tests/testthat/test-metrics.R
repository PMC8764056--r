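test_that("tortuosity index matches closed forms", {
  expect_equal(tortuosity_index(make_analytic_curve("line", length = 7)), 1,
               tolerance = 1e-9)
  expect_equal(tortuosity_index(make_analytic_curve("arc", radius = 1, angle = pi)),
               pi / 2, tolerance = 1e-4)
  expect_equal(tortuosity_index(make_analytic_curve("arc", radius = 1, angle = pi / 2)),
               pi / (2 * sqrt(2)), tolerance = 1e-4)
  closed <- centerline(data.frame(x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0), z = 0))
  expect_error(tortuosity_index(closed), class = "tortuometry_undefined_metric")
  near_closed <- centerline(data.frame(x = c(0, 1, 1, 0, 0.001),
                                       y = c(0, 0, 1, 1, 0), z = 0))
  expect_warning(tortuosity_index(near_closed), "near-divergent")
})

test_that("total curvature measures integrate to turning angles", {
  line_p <- curvature_profile(make_analytic_curve("line", length = 10))
  expect_lt(total_absolute_curvature(line_p), 1e-7)
  expect_lt(total_squared_curvature(line_p), 1e-7)

  for (r in c(1, 3)) {
    full <- curvature_profile(make_analytic_curve("arc", radius = r, angle = 2 * pi))
    expect_equal(total_absolute_curvature(full), 2 * pi, tolerance = 1e-3 / (2 * pi))
  }
  semi <- curvature_profile(make_analytic_curve("arc", radius = 1, angle = pi))
  expect_equal(total_absolute_curvature(semi), pi, tolerance = 1e-3 / pi)

  # kappa_tr of an arc is theta / r: halves when the radius doubles
  k2 <- total_squared_curvature(curvature_profile(
    make_analytic_curve("arc", radius = 2, angle = pi)))
  k4 <- total_squared_curvature(curvature_profile(
    make_analytic_curve("arc", radius = 4, angle = pi)))
  expect_equal(k2, pi / 2, tolerance = 1e-3)
  expect_equal(k2 / k4, 2, tolerance = 1e-3)
})

test_that("average and RMS curvature match piecewise-analytic oracles", {
  circ <- curvature_profile(make_analytic_curve("arc", radius = 5, angle = 1.9 * pi))
  expect_equal(average_absolute_curvature(circ), 0.2, tolerance = 1e-3)
  expect_equal(rms_curvature(circ), 0.2, tolerance = 1e-3)

  helix <- curvature_profile(make_analytic_curve("helix", a = 2, b = 1, turns = 1))
  expect_equal(average_absolute_curvature(helix), 0.4, tolerance = 1e-3)

  # semicircle r=1 plus straight tail of length pi:
  # kappa_a = pi/(2 pi) = 0.5, kappa_r = sqrt(pi/(2 pi)) = sqrt(0.5)
  mix <- curvature_profile(semicircle_with_tail(r = 1, tail = pi))
  expect_equal(average_absolute_curvature(mix), 0.5, tolerance = 1e-2 / 0.5)
  expect_equal(rms_curvature(mix), sqrt(0.5), tolerance = 1e-2)
})

test_that("squared-derivative curvature vanishes on constant-curvature curves", {
  for (cl in list(make_analytic_curve("line", length = 10),
                  make_analytic_curve("arc", radius = 5, angle = pi),
                  make_analytic_curve("helix", a = 2, b = 1, turns = 1))) {
    p <- curvature_derivative(curvature_profile(cl))
    expect_lt(average_squared_derivative_curvature(p), 1e-6)
  }
  expect_error(average_squared_derivative_curvature(
    curvature_profile(make_analytic_curve("line", length = 2))),
    class = "tortuometry_precondition_error")
})

test_that("squared-derivative curvature matches quadrature oracles", {
  # injected kappa(s) = s on [0,1]: integral of 1 over [0,1] / 1 = 1
  p <- curvature_derivative(fake_profile(seq(0, 1, by = 1e-3), seq(0, 1, by = 1e-3)))
  expect_equal(average_squared_derivative_curvature(p), 1, tolerance = 1e-3)

  # planar sine over one period vs brute-force evaluation of the analytic
  # curvature pipeline (quadrature in x with ds = sqrt(1 + y'^2) dx)
  sine <- make_analytic_curve("planar_sine", amplitude = 0.5, wavelength = 2 * pi,
                              span = 2 * pi)
  p2 <- curvature_derivative(curvature_profile(sine))
  got <- average_squared_derivative_curvature(p2)
  x <- seq(0, 2 * pi, length.out = 20001)
  yp <- 0.5 * cos(x); ypp <- -0.5 * sin(x)
  kx <- abs(ypp) / (1 + yp^2)^1.5
  ds <- sqrt(1 + yp^2)
  s <- cumsum(c(0, diff(x) * (ds[-1] + ds[-length(ds)]) / 2))
  dk <- fd_first_oracle(kx, s)
  L <- s[length(s)]
  want <- sum(diff(s) * (dk[-1]^2 + dk[-length(dk)]^2) / 2) / L
  expect_equal(got, want, tolerance = 0.02)
})

test_that("the full metric set mirrors the per-metric functions", {
  m_line <- compute_tortuosity(make_analytic_curve("line", length = 10),
                               resample = FALSE)
  expect_equal(m_line$tau, 1, tolerance = 1e-9)
  expect_lt(max(abs(c(m_line$kappa_ta, m_line$kappa_a, m_line$kappa_r,
                      m_line$kappa_d))), 1e-7)

  m_helix <- compute_tortuosity(make_analytic_curve("helix", a = 2, b = 1, turns = 2),
                                resample = FALSE)
  expect_equal(m_helix$kappa_a, 0.4, tolerance = 1e-3)
  expect_equal(m_helix$kappa_r, 0.4, tolerance = 1e-3)
  expect_lt(m_helix$kappa_d, 1e-6)

  branches <- list(LMCA = make_analytic_curve("line", length = 12),
                   LAD = make_analytic_curve("arc", radius = 3, angle = 2),
                   LCx = make_analytic_curve("helix", a = 2, b = 1, turns = 1))
  set <- compute_tortuosity_set(branches, case_id = "case001", spacing = 0.01)
  expect_equal(nrow(set), 3)
  expect_setequal(set$branch, c("LMCA", "LAD", "LCx"))
  expect_true(all(primary_metrics() %in% names(set)))
  expect_length(primary_metrics(), 4)
})

test_that("metrics obey the scale-transformation laws", {
  base <- make_analytic_curve("planar_sine", amplitude = 0.6, wavelength = 3,
                              span = 9, spacing = 0.01)
  m0 <- compute_tortuosity(base, resample = FALSE)
  for (lambda in c(0.5, 2, 10)) {
    scl <- scale_centerline(base, lambda)
    m1 <- compute_tortuosity(scl, spacing = 0.01 * lambda, resample = FALSE)
    expect_equal(m1$tau, m0$tau, tolerance = 1e-3)
    expect_equal(m1$kappa_ta, m0$kappa_ta, tolerance = 1e-3)
    expect_equal(m1$kappa_a, m0$kappa_a / lambda, tolerance = 1e-3)
    expect_equal(m1$kappa_r, m0$kappa_r / lambda, tolerance = 1e-3)
    expect_equal(m1$kappa_tr, m0$kappa_tr / lambda, tolerance = 1e-3)
    expect_equal(m1$kappa_d, m0$kappa_d / lambda^4, tolerance = 1e-3)
  }
})

test_that("appending a straight tail separates totals from averages", {
  bend <- curvature_profile(semicircle_with_tail(r = 1, tail = 1e-9 + 0.02))
  with_tail <- curvature_profile(semicircle_with_tail(r = 1, tail = pi))
  expect_equal(total_absolute_curvature(with_tail), total_absolute_curvature(bend),
               tolerance = 5e-3)
  expect_lt(average_absolute_curvature(with_tail), average_absolute_curvature(bend))
  expect_lt(rms_curvature(with_tail), rms_curvature(bend))
})

test_that("RMS curvature dominates average curvature", {
  profs <- list(curvature_profile(semicircle_with_tail()),
                curvature_profile(make_analytic_curve("helix", a = 2, b = 1, turns = 1)),
                curvature_profile(make_analytic_curve("planar_sine", amplitude = 0.5,
                                                      wavelength = 2 * pi, span = 2 * pi)))
  for (p in profs) expect_gte(rms_curvature(p), average_absolute_curvature(p))
  # equality only for constant curvature
  const <- curvature_profile(make_analytic_curve("arc", radius = 2, angle = pi))
  expect_equal(rms_curvature(const), average_absolute_curvature(const), tolerance = 1e-6)
  expect_gt(rms_curvature(profs[[1]]) - average_absolute_curvature(profs[[1]]), 1e-3)
})

test_that("metrics are stable when the resampling grid is refined", {
  th <- seq(0, 2, length.out = 60)
  cl <- centerline(data.frame(x = 3 * sin(th), y = 3 * (1 - cos(th)), z = 0.3 * th))
  m1 <- compute_tortuosity(cl, spacing = 0.01)
  m2 <- compute_tortuosity(cl, spacing = 0.005)
  for (nm in c("tau", "kappa_ta", "kappa_tr", "kappa_a", "kappa_r")) {
    expect_lt(abs(m2[[nm]] - m1[[nm]]) / abs(m2[[nm]]), 0.01)
  }
})
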