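test_that("standardize maps to mean 0 / SD 1 and is affine-invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(standardize(2.5 * x - 7), z)
  expect_equal(standardize(z), z)
  expect_error(standardize(rep(3, 10)), class = "tortuometry_degenerate_input")
  # standardizing never changes skewness or kurtosis
  expect_lt(abs(sample_skewness(z) - sample_skewness(x)), 1e-9)
  expect_lt(abs(excess_kurtosis(z) - excess_kurtosis(x)), 1e-9)
})

test_that("skewness and kurtosis match moment oracles and known populations", {
  expect_lt(abs(sample_skewness(c(-2, -1, 0, 1, 2))), 1e-12)
  expect_equal(sample_skewness(c(0, 0, 0, 1)), skew_oracle(c(0, 0, 0, 1)))
  expect_gt(sample_skewness(c(0, 0, 0, 1)), 0)
  two_pt <- rep(c(-1, 1), 50)
  expect_equal(excess_kurtosis(two_pt), kurt_oracle(two_pt))

  set.seed(21)
  ex <- rexp(1e5)
  expect_equal(sample_skewness(ex), 2, tolerance = 0.1 / 2)
  nrm <- rnorm(1e5)
  expect_lt(abs(excess_kurtosis(nrm)), 0.1)
  lap <- rexp(1e5) * sample(c(-1, 1), 1e5, replace = TRUE)
  expect_equal(excess_kurtosis(lap), 3, tolerance = 0.2 / 3)

  expect_error(sample_skewness(c(1, 2)), class = "tortuometry_degenerate_input")
  expect_error(excess_kurtosis(rep(1, 10)), class = "tortuometry_degenerate_input")
})

test_that("significance classes follow the inclusive star thresholds", {
  expect_equal(significance_class(0.0005), "***")
  expect_equal(significance_class(0.001), "***")
  expect_equal(significance_class(0.01), "**")
  expect_equal(significance_class(0.05), "*")
  expect_equal(significance_class(0.051), "")
  expect_equal(significance_class(0.86), "")
  # monotone non-increasing star count in p
  p <- sort(runif(50))
  stars <- nchar(significance_class(p))
  expect_true(all(diff(stars) <= 0))
  expect_error(significance_class(1.2), class = "tortuometry_invalid_input")
})

test_that("OLS matches the closed-form normal equations to 1e-10", {
  d <- data.frame(x = 1:10)
  d$y <- 2 * d$x + 1
  fit <- suppressWarnings(ols_fit(d, "y", "x"))  # lm warns on a perfect fit
  expect_equal(unname(coef(fit$fit)), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  expect_equal(fit$adj_r2, 1)

  # hand-computed 3-point case: slope 2, RSS = 2/3, TSS = 26/3, R^2 = 12/13
  d3 <- data.frame(x = c(0, 1, 2), y = c(0, 1, 4))
  f3 <- ols_fit(d3, "y", "x")
  expect_equal(unname(coef(f3$fit))[2], 2, tolerance = 1e-12)
  expect_equal(f3$r2, 12 / 13, tolerance = 1e-12)

  set.seed(9)
  for (k in 1:3) {
    n <- sample(8:20, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n)
    dd <- data.frame(y = y, X)
    fit <- ols_fit(dd, "y", names(dd)[-1])
    want <- ols_oracle(y, X)
    expect_equal(unname(coef(fit$fit)), want$beta, tolerance = 1e-10)
    expect_equal(fit$r2, want$r2, tolerance = 1e-10)
    expect_equal(fit$adj_r2, want$adj_r2, tolerance = 1e-10)
    expect_equal(fit$p_value, want$p, tolerance = 1e-10)
    expect_lte(fit$adj_r2, fit$r2)
  }

  # pure-noise predictors: adjusted R^2 dips negative across seeds
  neg <- vapply(1:40, function(s) {
    set.seed(100 + s)
    dd <- data.frame(y = rnorm(20), x = rnorm(20))
    ols_fit(dd, "y", "x")$adj_r2
  }, numeric(1))
  expect_gt(sum(neg < 0), 10)

  expect_error(ols_fit(data.frame(y = 1:3, x = 1:3), "y", c("x", "x")),
               class = "tortuometry_insufficient_data")
  dd <- data.frame(y = rnorm(10), a = 1:10, b = 2 * (1:10))
  expect_error(ols_fit(dd, "y", c("a", "b")),
               class = "tortuometry_collinearity_error")
})

test_that("tidy and glance expose the fit in broom style", {
  d <- data.frame(x = rnorm(30))
  d$y <- 0.5 * d$x + rnorm(30, sd = 0.2)
  fit <- ols_fit(d, "y", "x")
  td <- tidy(fit)
  expect_setequal(names(td), c("term", "estimate", "std.error", "statistic",
                               "p.value", "conf.low", "conf.high"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  expect_equal(gl$stars, significance_class(gl$p_value))
})

fake_cohort <- function(n = 60, beta1 = 0, seed = 5) {
  set.seed(seed)
  branches <- c("LMCA", "LAD", "LCx")
  d <- tidyr::expand_grid(case_id = sprintf("c%03d", 1:n), branch = branches)
  d$tau <- 1 + rexp(nrow(d), 50)
  d$kappa_a <- rnorm(nrow(d), 0.45, 0.1)
  d$kappa_r <- d$kappa_a * runif(nrow(d), 1, 1.6)
  d$kappa_d <- rexp(nrow(d), 15)
  d$L <- 10
  d$low_tawss_fraction <- pmin(pmax(0.15 + beta1 * d$kappa_a +
                                      rnorm(nrow(d), 0, 0.1), 0), 1)
  d
}

test_that("the cohort analysis grid covers 4 metrics x 4 segments", {
  an <- run_cohort_analysis(fake_cohort())
  expect_s3_class(an, "tortuometry_cohort_analysis")
  expect_equal(nrow(an), 16)
  expect_setequal(unique(an$segment), c("LMCA", "LAD", "LCx", "bifurcation"))
  expect_setequal(unique(an$metric), primary_metrics())
  expect_true(all(an$adj_r2 <= an$r2))
  expect_true(all(an$stars == significance_class(an$p_value)))

  # null cohort: adjusted R^2 hovers near zero, no strong effects
  expect_lt(mean(an$adj_r2), 0.05)

  rep <- format_cohort_report(an)
  expect_true(any(grepl("kappa_a", rep)))
  expect_error(run_cohort_analysis(dplyr::select(fake_cohort(), -"branch")),
               class = "tortuometry_invalid_input")
  dup <- fake_cohort()[c(1, 1, 2:10), ]
  expect_error(run_cohort_analysis(dup), class = "tortuometry_invalid_input")
})

test_that("whole-bifurcation aggregation is length-weighted and overridable", {
  d <- fake_cohort(n = 20)
  agg <- aggregate_bifurcation(d)
  expect_equal(nrow(agg), 20)
  one <- dplyr::filter(d, .data$case_id == "c001")
  expect_equal(agg$kappa_a[agg$case_id == "c001"],
               weighted.mean(one$kappa_a, one$L))
  d$whole_fraction <- 0.33
  agg2 <- aggregate_bifurcation(d)
  expect_true(all(agg2$low_tawss_fraction == 0.33))
})

test_that("distribution shape recovers known cohort asymmetries", {
  d <- fake_cohort(n = 80, seed = 13)
  sh <- distribution_shape(d)
  expect_equal(nrow(sh), 16)
  # tau was drawn right-skewed, kappa_a symmetric
  tau_row <- dplyr::filter(sh, .data$metric == "tau", .data$segment == "LMCA")
  expect_gt(tau_row$skewness, 0.5)
  ka <- dplyr::filter(sh, .data$metric == "kappa_a", .data$segment == "LMCA")
  expect_lt(abs(ka$skewness), 1)
})
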