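test_that("distribution families are parameterised as documented", {
  # gamma moment matching: Table-3-style mean 11.60, SE 4.10
  p <- uncertain_parameter("consult", "gamma_mean_se", mean = 11.60, se = 4.10)
  shape <- (11.60 / 4.10)^2
  scale <- 4.10^2 / 11.60
  expect_equal(shape, 8.006, tolerance = 1e-3)
  expect_equal(scale, 1.4491, tolerance = 1e-4)
  set.seed(31)
  draws <- sample_parameter(p, 2e4)
  expect_equal(mean(draws), 11.60, tolerance = 0.1)
  expect_equal(sd(draws), 4.10, tolerance = 0.1)

  # beta from proportion and effective count: mean is p exactly
  b <- uncertain_parameter("removal", "beta_count", p = 0.07, n = 30)
  alpha <- 0.07 * 30; beta <- 0.93 * 30
  expect_equal(alpha / (alpha + beta), 0.07)
  set.seed(32)
  bd <- sample_parameter(b, 2e4)
  expect_equal(mean(bd), 0.07, tolerance = 0.01)
  expect_true(all(bd >= 0 & bd <= 1))

  # relative risk: lognormal with sigma from the CI width
  r <- uncertain_parameter("rr", "relative_risk", rr = 1.2,
                           ci = c(1.1, 1.309))
  set.seed(33)
  rd <- sample_parameter(r, 2e4)
  expect_equal(median(rd), 1.2, tolerance = 0.01)
  expect_equal(unname(quantile(rd, 0.975)), 1.309, tolerance = 0.02)
})

test_that("degenerate parameters collapse to point masses", {
  expect_equal(sample_parameter(
    uncertain_parameter("a", "normal", mean = 5, se = 0), 10), rep(5, 10))
  expect_equal(sample_parameter(
    uncertain_parameter("b", "gamma_mean_se", mean = 2, se = 0), 10),
    rep(2, 10))
  expect_equal(sample_parameter(
    uncertain_parameter("c", "beta_count", p = 0, n = 30), 10), rep(0, 10))
  expect_equal(sample_parameter(
    uncertain_parameter("d", "relative_risk", rr = 1.1, ci = c(1.1, 1.1)),
    10), rep(1.1, 10))
})

test_that("zero-mean gamma degenerates to a half-normal", {
  p <- uncertain_parameter("mort2", "gamma_mean_se", mean = 0, se = 0.0002)
  set.seed(34)
  expect_message(draws <- sample_parameter(p, 5e4), "half-normal")
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), 0.0002 * sqrt(2 / pi), tolerance = 0.03)
})

test_that("parameter validation catches malformed inputs", {
  expect_error(uncertain_parameter("x", "normal", mean = 1, se = -1))
  expect_error(uncertain_parameter("x", "beta_count", p = 1.5, n = 10))
  expect_error(uncertain_parameter("x", "relative_risk", rr = 1.2,
                                   ci = c(1.25, 1.3)))
})

test_that("ICER summary ranks dominance below all paying iterations", {
  all_saving <- data.frame(dalys_averted = c(10, 20, 30),
                           net_cost = c(-5, -1, -10))
  s1 <- summarize_icer(all_saving)
  expect_equal(s1$mean, "dominant")
  expect_equal(s1$lower, "dominant")
  expect_equal(s1$upper, "dominant")
  expect_equal(format(s1), "dominant (dominant - dominant)")

  all_paying <- data.frame(dalys_averted = rep(10, 4),
                           net_cost = c(100, 200, 300, 400))
  s2 <- summarize_icer(all_paying)
  expect_true(is.numeric(s2$lower) && is.numeric(s2$upper))
  expect_equal(s2$lower, 10)   # 100/10
  expect_equal(s2$upper, 40)
  expect_equal(s2$mean, mean(c(100, 200, 300, 400)) / 10)

  # 50/50 mixture: lower bound dominant, upper numeric
  mix <- data.frame(dalys_averted = rep(10, 40),
                    net_cost = c(rep(-50, 20), seq(100, 2000, 100)))
  s3 <- summarize_icer(mix)
  expect_equal(s3$lower, "dominant")
  expect_true(is.numeric(s3$upper))
  s3b <- summarize_icer(rbind(mix,
                              data.frame(dalys_averted = -1, net_cost = 10)))
  expect_equal(s3b$n_nonpositive_dalys, 1)
})

test_that("probability below threshold is an exact count ratio", {
  pts <- data.frame(dalys_averted = c(10, 10, 10),
                    net_cost = c(-5, 50, 500))   # ICERs: saving, 5, 50
  expect_equal(probability_below(pts, 20), 2 / 3)
  expect_equal(probability_below(pts, 1e9), 1)
  expect_equal(probability_below(pts, 0), mean(pts$net_cost < 0))
  # monotone in the threshold
  set.seed(35)
  rnd <- data.frame(dalys_averted = rnorm(200, 5, 3),
                    net_cost = rnorm(200, 100, 300))
  probs <- vapply(c(0, 10, 50, 200, 1000), probability_below,
                  1.0, plane = rnd)
  expect_true(all(diff(probs) >= 0))
  # all cost-saving: probability 1 at any positive threshold
  saving <- data.frame(dalys_averted = c(1, 2), net_cost = c(-1, -2))
  expect_equal(probability_below(saving, 0.01), 1)
})

test_that("Monte Carlo is seed-deterministic and degenerate-exact", {
  ctx <- default_ctx()
  cfg <- run_config("bmi40", n_iterations = 40, seed = 5)
  spec <- intervention_spec()

  a <- run_monte_carlo(ctx, cfg, spec)
  b <- run_monte_carlo(ctx, cfg, spec)
  expect_identical(a$ce_plane, b$ce_plane)
  expect_identical(a$mean, b$mean)

  # degenerate distributions reproduce the point-estimate run exactly
  point <- evaluate_model(ctx, cfg, spec)
  deg <- run_monte_carlo(ctx, cfg, spec,
                         parameters = degenerate_parameters(ctx, spec),
                         n_iter = 5)
  expect_equal(unique(deg$ce_plane$dalys_averted), point$dalys_averted)
  expect_equal(unique(deg$ce_plane$net_cost), point$net_cost)
})

test_that("Monte Carlo standard error of the mean shrinks as 1/sqrt(n)", {
  ctx <- default_ctx()
  spec <- intervention_spec()
  small <- run_monte_carlo(ctx, run_config("bmi40", seed = 6), spec,
                           n_iter = 200)
  large <- run_monte_carlo(ctx, run_config("bmi40", seed = 6), spec,
                           n_iter = 800)
  se_small <- sd(small$ce_plane$dalys_averted) / sqrt(200)
  se_large <- sd(large$ce_plane$dalys_averted) / sqrt(800)
  expect_gt(se_large / se_small, 0.4)
  expect_lt(se_large / se_small, 0.6)
})
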