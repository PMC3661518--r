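test_that("lognormal moment matching round-trips mean and SD", {
  for (case in list(c(27, 5), c(24, 3), c(30, 6), c(27, 1e-4))) {
    par <- lognormal_from_mean_sd(case[1], case[2])
    back_mean <- exp(par$mu + par$sigma^2 / 2)
    back_sd <- back_mean * sqrt(expm1(par$sigma^2))
    expect_equal(back_mean, case[1], tolerance = 1e-10)
    expect_equal(back_sd, case[2], tolerance = 1e-10)
  }
  # sd -> 0 limit
  par0 <- lognormal_from_mean_sd(27, 0)
  expect_equal(par0$sigma, 0)
  expect_equal(par0$mu, log(27))
  expect_error(lognormal_from_mean_sd(-1, 5), "positive")
  expect_error(lognormal_from_mean_sd(27, -1), "non-negative")
})

test_that("lognormal mean matches quadrature at mean 27, sd 5", {
  par <- lognormal_from_mean_sd(27, 5)
  num <- integrate(function(x) x * dlnorm(x, par$mu, par$sigma), 0, Inf,
                   rel.tol = 1e-12)$value
  expect_equal(num, 27, tolerance = 1e-6)
})

test_that("category proportions telescope to 1 and match quadrature", {
  set.seed(11)
  for (k in 1:25) {
    ex <- bmi_exposure(runif(1, 24, 30), runif(1, 3, 6))
    expect_equal(sum(ex$p), 1, tolerance = 1e-12)
    expect_true(all(ex$p >= 0))
    oracle <- oracle_category_proportions(ex$mu, ex$sigma)
    expect_equal(category_proportions(ex), oracle, tolerance = 1e-8)
  }
})

test_that("degenerate exposure puts all mass in the containing category", {
  ex <- bmi_exposure(27, 0)
  expect_equal(ex$p, c(0, 1, 0, 0, 0))
  expect_equal(ex$category_mean[2], 27)
})

test_that("category means are truncated-lognormal means, strictly increasing", {
  set.seed(12)
  for (k in 1:10) {
    ex <- bmi_exposure(runif(1, 24, 30), runif(1, 3, 6))
    lo <- c(0, ex$cutpoints)
    hi <- c(ex$cutpoints, Inf)
    for (i in 1:5) {
      expect_equal(ex$category_mean[i],
                   oracle_truncated_mean(ex$mu, ex$sigma, lo[i], hi[i]),
                   tolerance = 1e-8)
    }
    expect_true(all(diff(ex$category_mean) > 0))
  }
})

test_that("category relative risks follow the power law", {
  ex <- bmi_exposure(27, 5)
  expect_equal(category_relative_risks(1, ex), rep(1, 5))
  rr <- category_relative_risks(1.05, ex)
  expect_equal(rr[1], 1)
  expect_true(all(diff(rr) >= 0))
  # independent power evaluation with quadrature means
  m <- vapply(1:5, function(i)
    oracle_truncated_mean(ex$mu, ex$sigma, c(0, 25, 30, 35, 40)[i],
                          c(25, 30, 35, 40, Inf)[i]), 1.0)
  expect_equal(rr, 1.05^(m - m[1]), tolerance = 1e-7)
  # spec-style magnitude check: a 20-unit gap at 1.05/unit
  expect_equal(1.05^20, 2.6533, tolerance = 1e-4)
  expect_error(category_relative_risks(0.9, ex), ">= 1")
})

test_that("risk shifting scales eligible categories and floors at 1", {
  rr <- c(1, 1.2, 1.5, 1.8, 2.0)
  expect_equal(shift_relative_risks(rr, 1.05, 0, 5), rr)
  shifted <- shift_relative_risks(rr, 1.05, 10, 5)
  expect_equal(shifted[5], 2.0 * 1.05^(-10), tolerance = 1e-12)
  expect_equal(shifted[5], 1.2278, tolerance = 1e-4)
  expect_equal(shifted[1:4], rr[1:4])
  # large delta floors at 1 and only eligible categories move
  floored <- shift_relative_risks(rr, 1.05, 100, 4:5)
  expect_equal(floored, c(1, 1.2, 1.5, 1, 1))
})

test_that("potential impact fraction matches hand summation and bounds", {
  expect_equal(potential_impact_fraction(c(0.8, 0.2), c(1, 2), c(1, 1.5)),
               0.1 / 1.2, tolerance = 1e-12)
  expect_equal(potential_impact_fraction(c(0.5, 0.5), c(1, 3), c(1, 3)), 0)
  expect_equal(potential_impact_fraction(c(1, 0), c(1, 5), c(1, 1)), 0)
  expect_error(potential_impact_fraction(c(0.5, 0.4), c(1, 2), c(1, 2)),
               "sum to 1")
  expect_error(potential_impact_fraction(c(0.5, 0.5), c(1, 2), c(1, 2.5)),
               "exceed")
})

test_that("PIF is non-decreasing in delta_bmi and rr_unit, and in [0, 1)", {
  ex <- bmi_exposure(27, 5)
  for (scenario in c("bmi40", "bmi35")) {
    elig <- eligible_categories(scenario)
    grid_rr <- c(1, 1.02, 1.05, 1.1, 1.2, 1.4)
    grid_delta <- c(0, 1, 2, 5, 8, 10)
    pif <- outer(grid_rr, grid_delta, Vectorize(function(r, d) {
      rr <- category_relative_risks(r, ex)
      potential_impact_fraction(ex$p, rr,
                                shift_relative_risks(rr, r, d, elig))
    }))
    expect_true(all(pif >= 0 & pif < 1))
    expect_true(all(apply(pif, 1, function(row) all(diff(row) >= -1e-12))))
    expect_true(all(apply(pif, 2, function(col) all(diff(col) >= -1e-12))))
  }
})

test_that("categorical PIF tracks the continuous PIF for moderate RRs", {
  # The categorical approximation is accurate while rr_unit stays below
  # ~1.15/BMI unit; beyond that the exponential RR makes the continuous
  # integral tail-dominated and the two diverge (see the methods vignette).
  set.seed(13)
  for (k in 1:30) {
    mn <- runif(1, 24, 30); s <- runif(1, 3, 6)
    rr <- runif(1, 1.0, 1.15); dl <- runif(1, 0, 10)
    sc <- sample(c("bmi40", "bmi35"), 1)
    cutoff <- if (sc == "bmi40") 40 else 35
    expect_lt(abs(categorical_pif(mn, s, rr, dl, sc) -
                    oracle_continuous_pif(mn, s, rr, dl, cutoff)), 0.02)
  }
})

test_that("incidence adjustment is the PIF complement product", {
  expect_equal(adjust_incidence(0.01, 0.0833333), 0.0091667,
               tolerance = 1e-5)
  expect_equal(adjust_incidence(0.01, 0), 0.01)
  expect_equal(adjust_incidence(0, 0.5), 0)
})

test_that("BMI trend shifts the mean, capped at 20 years", {
  ex <- bmi_exposure(27, 5)
  expect_identical(apply_bmi_trend(ex, 0, 0.05), ex)
  expect_identical(apply_bmi_trend(ex, 10, 0), ex)
  shifted <- apply_bmi_trend(ex, 25, 0.05)
  expect_equal(shifted$mean, 28)          # min(25, 20) * 0.05 = 1.0
  expect_equal(shifted$sd, 5)
  expect_equal(shifted$p, bmi_exposure(28, 5)$p)
})
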