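#' An uncertain model parameter and its sampling distribution
#'
#' The four distribution families used in the probabilistic sensitivity
#' analysis, parameterised the way burden-of-disease uncertainty tables
#' print them:
#' * `normal`: mean and SE;
#' * `beta_count`: a proportion `p` and effective count `N`, giving
#'   `alpha = p N`, `beta = (1 - p) N`;
#' * `gamma_mean_se`: moment-matched, `shape = (mean/SE)^2`,
#'   `scale = SE^2/mean`; a zero mean cannot be a proper gamma and
#'   degenerates to a half-normal with scale SE (logged per run);
#' * `relative_risk`: lognormal on `log(RR)` with
#'   `sigma = (log(hi) - log(lo)) / (2 * 1.96)` from a 95% CI.
#'
#' @param name Parameter name.
#' @param family One of `"normal"`, `"beta_count"`, `"gamma_mean_se"`,
#'   `"relative_risk"`.
#' @param mean,se Mean and standard error (normal, gamma families).
#' @param p,n Proportion and effective sample size (beta family).
#' @param rr,ci Relative risk and its 95% CI bounds (length-2, bracketing
#'   `rr`).
#' @param role Optional tag telling [run_monte_carlo()] where the draw
#'   feeds into the model.
#' @return An object of class `uncertain_parameter`.
#' @export
uncertain_parameter <- function(name,
                                family = c("normal", "beta_count",
                                           "gamma_mean_se", "relative_risk"),
                                mean = NULL, se = NULL, p = NULL, n = NULL,
                                rr = NULL, ci = NULL, role = NULL) {
  family <- match.arg(family)
  switch(family,
    normal = {
      stopifnot(is.numeric(mean), is.numeric(se), se >= 0)
    },
    beta_count = {
      stopifnot(is.numeric(p), p >= 0, p <= 1, is.numeric(n), n >= 1)
    },
    gamma_mean_se = {
      stopifnot(is.numeric(mean), mean >= 0, is.numeric(se), se >= 0)
    },
    relative_risk = {
      stopifnot(is.numeric(rr), rr > 0, length(ci) == 2,
                ci[1] <= rr, rr <= ci[2], ci[1] > 0)
    })
  structure(list(name = name, family = family, mean = mean, se = se,
                 p = p, n = n, rr = rr, ci = ci, role = role),
            class = "uncertain_parameter")
}

#' Draw from an uncertain parameter's distribution
#'
#' Uses the current RNG state; degenerate parameters (SE = 0, p in {0, 1})
#' return the point estimate for every draw.
#'
#' @param param An [uncertain_parameter()].
#' @param n_draws Number of draws.
#' @return Numeric vector of length `n_draws`.
#' @export
sample_parameter <- function(param, n_draws = 1) {
  stopifnot(inherits(param, "uncertain_parameter"))
  switch(param$family,
    normal = {
      if (param$se == 0) rep(param$mean, n_draws)
      else stats::rnorm(n_draws, param$mean, param$se)
    },
    beta_count = {
      if (param$p %in% c(0, 1)) rep(param$p, n_draws)
      else stats::rbeta(n_draws, param$p * param$n, (1 - param$p) * param$n)
    },
    gamma_mean_se = {
      if (param$se == 0) {
        rep(param$mean, n_draws)
      } else if (param$mean == 0) {
        message("gamma parameter '", param$name,
                "' has zero mean; sampling half-normal(scale = SE)")
        abs(stats::rnorm(n_draws, 0, param$se))
      } else {
        shape <- (param$mean / param$se)^2
        if (shape < 1)
          message("gamma parameter '", param$name,
                  "' has SE > mean (shape ", round(shape, 3), " < 1)")
        stats::rgamma(n_draws, shape = shape,
                      scale = param$se^2 / param$mean)
      }
    },
    relative_risk = {
      sigma <- (log(param$ci[2]) - log(param$ci[1])) / (2 * 1.96)
      if (sigma == 0) rep(param$rr, n_draws)
      else stats::rlnorm(n_draws, log(param$rr), sigma)
    })
}

#' Point estimate of an uncertain parameter
#' @param param An [uncertain_parameter()].
#' @return The distribution's central value.
#' @export
parameter_point <- function(param) {
  switch(param$family,
    normal = param$mean,
    beta_count = param$p,
    gamma_mean_se = param$mean,
    relative_risk = param$rr)
}

#' Default uncertainty parameter set
#'
#' The intervention-side uncertainty set: weight loss after surgery
#' (normal, 31.97 kg, SE 1.62), post-surgical mortality in years one and two
#' (gamma, 0.0006 SE 0.0003 and 0 SE 0.0002 -- the latter degenerating to a
#' half-normal), annual long-term complication risks (beta with N = 1120:
#' gastric prolapse 0.01, band erosion 0.001, port infection 0.002, band
#' removal 0.004), short-term complication risks (beta with N = 30) and
#' outpatient consultation frequencies (gamma) feeding the initial-cost
#' scaling, plus one relative-risk parameter per modelled disease taken
#' from the input set's synthetic CIs. Disability weights, offset unit
#' costs and maintenance costs carry no uncertainty information and stay
#' fixed.
#'
#' @param ctx A [model_context()] supplying the per-disease relative risks.
#' @return A list of [uncertain_parameter()] objects.
#' @export
default_uncertain_parameters <- function(ctx) {
  pars <- list(
    uncertain_parameter("weight_loss_kg", "normal", mean = 31.97, se = 1.62,
                        role = "weight_loss"),
    uncertain_parameter("mortality_first_year", "gamma_mean_se",
                        mean = 0.0006, se = 0.0003, role = "mortality_y1"),
    uncertain_parameter("mortality_second_year", "gamma_mean_se",
                        mean = 0, se = 0.0002, role = "mortality_y2"),
    uncertain_parameter("gastric_prolapse", "beta_count", p = 0.01,
                        n = 1120, role = "longterm_complication"),
    uncertain_parameter("band_erosion", "beta_count", p = 0.001, n = 1120,
                        role = "longterm_complication"),
    uncertain_parameter("port_infection", "beta_count", p = 0.002, n = 1120,
                        role = "longterm_complication"),
    uncertain_parameter("band_removal", "beta_count", p = 0.004, n = 1120,
                        role = "longterm_complication"),
    uncertain_parameter("band_removal_replacement_2y", "beta_count",
                        p = 0.07, n = 30, role = "initial_resource"),
    uncertain_parameter("port_infection_admission_2y", "beta_count",
                        p = 0.03, n = 30, role = "initial_resource"),
    uncertain_parameter("band_removal_2y", "beta_count", p = 0.03, n = 30,
                        role = "initial_resource"),
    uncertain_parameter("consult_surgeon", "gamma_mean_se", mean = 11.60,
                        se = 4.10, role = "initial_resource"),
    uncertain_parameter("consult_surgeon_adjustment", "gamma_mean_se",
                        mean = 10.27, se = 4.58, role = "initial_resource"),
    uncertain_parameter("consult_respiratory", "gamma_mean_se", mean = 0.43,
                        se = 1.14, role = "initial_resource"),
    uncertain_parameter("consult_dietician", "gamma_mean_se", mean = 0.10,
                        se = 0.31, role = "initial_resource")
  )
  rr <- ctx$rr_point
  for (j in seq_len(nrow(rr))) {
    pars[[length(pars) + 1L]] <- uncertain_parameter(
      paste0("rr_", rr$disease[j]), "relative_risk",
      rr = rr$rr_unit[j], ci = c(rr$rr_lo[j], rr$rr_hi[j]), role = "rr")
  }
  pars
}

# Translate one row of joint draws into the parameter list consumed by
# evaluate_model(). The initial-resource draws scale the variable share
# (30%) of the initial surgery cost; long-term complication draws scale the
# annual complication cost proportionally to their summed point risk.
.draws_to_params <- function(draws, parameters, ctx, spec) {
  roles <- vapply(parameters, function(p) p$role %||% "", "")
  points <- vapply(parameters, parameter_point, 1.0)
  g <- function(role) which(roles == role)

  peak <- max(0, draws[g("weight_loss")])
  lt <- g("longterm_complication")
  comp_scale <- if (length(lt)) sum(draws[lt]) / sum(points[lt]) else 1
  res <- g("initial_resource")
  surg_scale <- if (length(res)) 0.7 + 0.3 * sum(draws[res]) / sum(points[res])
                else 1
  list(
    peak_loss_kg = peak,
    two_year_loss_kg = spec$two_year_loss_kg *
      peak / spec$peak_loss_kg,
    mortality_first_year = min(1, draws[g("mortality_y1")]),
    mortality_second_year = min(1, draws[g("mortality_y2")]),
    rr_unit = pmax(1, draws[g("rr")]),
    complication_cost_scale = comp_scale,
    surgery_cost_scale = max(0, surg_scale)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte Carlo uncertainty analysis
#'
#' Redraws all uncertain parameters jointly `n_iter` times, evaluates the
#' full pipeline at each draw, and summarises DALYs averted, cost
#' components, net cost and the ICER with 95% uncertainty intervals,
#' cost-effectiveness probabilities and the cost-effectiveness plane.
#' Deterministic given `seed`. Iterations failing input validation are
#' skipped and counted; more than 1% failures aborts the run.
#'
#' @param ctx A [model_context()].
#' @param config A [run_config()]; supplies scenario, discounting and
#'   costing switches.
#' @param spec An [intervention_spec()].
#' @param parameters List of [uncertain_parameter()]s, default
#'   [default_uncertain_parameters()].
#' @param n_iter Iterations, default `config$n_iterations` (3000).
#' @param seed RNG seed, default `config$seed`.
#' @return An object of class `psa_summary`.
#' @export
run_monte_carlo <- function(ctx, config, spec = intervention_spec(),
                            parameters = default_uncertain_parameters(ctx),
                            n_iter = config$n_iterations,
                            seed = config$seed) {
  stopifnot(inherits(ctx, "model_context"), n_iter >= 1)
  set.seed(seed)
  np <- length(parameters)
  draws <- matrix(0, n_iter, np)
  for (j in seq_len(np))
    draws[, j] <- suppressMessages(sample_parameter(parameters[[j]], n_iter))

  cols <- c("dalys_averted", "net_cost", "cost_intervention",
            "cost_maintenance", "cost_offsets", "cost_unrelated")
  out <- matrix(NA_real_, n_iter, length(cols),
                dimnames = list(NULL, cols))
  failed <- 0L
  for (i in seq_len(n_iter)) {
    params <- .draws_to_params(draws[i, ], parameters, ctx, spec)
    r <- tryCatch(evaluate_model(ctx, config, spec, params),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failed <- failed + 1L
      if (failed > max(1, 0.01 * n_iter))
        stop("more than 1% of Monte Carlo iterations failed; last error: ",
             conditionMessage(r), call. = FALSE)
      next
    }
    out[i, ] <- c(r$dalys_averted, r$net_cost, r$cost_intervention,
                  r$cost_maintenance, r$cost_offsets, r$cost_unrelated)
  }
  ok <- stats::complete.cases(out)
  plane <- data.frame(iteration = seq_len(n_iter)[ok], out[ok, , drop = FALSE])

  qs <- apply(out[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  means <- colMeans(out[ok, , drop = FALSE])
  structure(
    list(n_iter = n_iter, n_failed = failed, seed = seed,
         scenario = config$scenario, config_hash = config_hash(config),
         mean = means, lower = qs[1, ], upper = qs[2, ],
         icer_summary = summarize_icer(plane),
         prob_cost_saving = mean(plane$net_cost < 0),
         prob_below_10k = probability_below(plane, 10000),
         prob_below_50k = probability_below(plane, 50000),
         ce_plane = plane),
    class = "psa_summary"
  )
}

#' Rank-based ICER summary with dominance labels
#'
#' Iterations on the cost-effectiveness plane are ranked by favourability:
#' cost-saving iterations (net cost < 0, DALYs averted > 0) sit below all
#' positive-ICER iterations, ordered by net cost; positive-net iterations
#' are ordered by their ICER. The 2.5th/97.5th percentile positions of this
#' ranking give the uncertainty interval, reported as `"dominant"` when the
#' position falls in the cost-saving block. The mean is reported as
#' `"dominant"` when the mean net cost is negative with positive mean DALYs,
#' otherwise as the ratio of mean net cost to mean DALYs averted.
#' Iterations with non-positive DALYs averted are excluded from the ranking
#' and reported separately.
#'
#' @param plane Data frame with columns `dalys_averted` and `net_cost`
#'   (at least 2 rows).
#' @return An object of class `icer_summary`: list with `mean`, `lower`,
#'   `upper` (numeric AU$/DALY or the string `"dominant"`) and
#'   `n_nonpositive_dalys`.
#' @export
summarize_icer <- function(plane) {
  stopifnot(nrow(plane) >= 2)
  valid <- plane$dalys_averted > 0
  saving <- valid & plane$net_cost < 0
  paying <- valid & plane$net_cost >= 0
  icers <- plane$net_cost[paying] / plane$dalys_averted[paying]
  ranked <- c(sort(plane$net_cost[saving]), sort(icers))
  labels <- c(rep(TRUE, sum(saving)), rep(FALSE, sum(paying)))
  n <- length(ranked)
  pick <- function(q) {
    k <- min(n, max(1L, ceiling(q * n)))
    if (labels[k]) "dominant" else ranked[k]
  }
  mean_net <- mean(plane$net_cost)
  mean_dalys <- mean(plane$dalys_averted)
  mean_icer <- if (mean_net < 0 && mean_dalys > 0) "dominant"
               else mean_net / mean_dalys
  structure(
    list(mean = mean_icer, lower = pick(0.025), upper = pick(0.975),
         n_nonpositive_dalys = sum(!valid)),
    class = "icer_summary"
  )
}

#' @export
format.icer_summary <- function(x, ...) {
  f <- function(v) if (is.character(v)) v
                   else paste0("$", format(round(v), big.mark = " "))
  paste0(f(x$mean), " (", f(x$lower), " - ", f(x$upper), ")")
}

#' @export
print.icer_summary <- function(x, ...) {
  cat("ICER mean (95% UI):", format(x), "\n")
  if (x$n_nonpositive_dalys > 0)
    cat("  iterations with DALYs averted <= 0:", x$n_nonpositive_dalys, "\n")
  invisible(x)
}

#' Probability that the ICER lies below a willingness-to-pay threshold
#'
#' Counts the iterations that are cost-saving (net cost < 0) or have
#' positive health gain bought at less than `threshold` per DALY
#' (`net_cost < threshold * dalys_averted`).
#'
#' @param plane Data frame with columns `dalys_averted` and `net_cost`.
#' @param threshold Willingness to pay, AU$ per DALY averted (`>= 0`).
#' @return Exact count ratio in `[0, 1]`.
#' @export
probability_below <- function(plane, threshold) {
  stopifnot(nrow(plane) >= 1, threshold >= 0)
  hit <- plane$net_cost < 0 |
    (plane$dalys_averted > 0 &
       plane$net_cost < threshold * plane$dalys_averted)
  mean(hit)
}

#' @export
print.psa_summary <- function(x, ...) {
  cat("Probabilistic sensitivity analysis [", x$scenario, "], ",
      x$n_iter, " iterations (", x$n_failed, " failed), seed ", x$seed,
      ", config ", x$config_hash, "\n", sep = "")
  m <- function(v) format(round(v / 1e6), big.mark = " ")
  cat("  DALYs averted:  ", format(round(x$mean["dalys_averted"]),
                                   big.mark = " "),
      " (", format(round(x$lower["dalys_averted"]), big.mark = " "), " - ",
      format(round(x$upper["dalys_averted"]), big.mark = " "), ")\n",
      sep = "")
  cat("  net cost:       $", m(x$mean["net_cost"]), "m ($",
      m(x$lower["net_cost"]), "m - $", m(x$upper["net_cost"]), "m)\n",
      sep = "")
  cat("  ", format(x$icer_summary), "\n", sep = "")
  cat("  P(cost saving) = ", sprintf("%.1f%%", 100 * x$prob_cost_saving),
      "; P(ICER < $10k) = ", sprintf("%.1f%%", 100 * x$prob_below_10k),
      "; P(ICER < $50k) = ", sprintf("%.1f%%", 100 * x$prob_below_50k),
      "\n", sep = "")
  invisible(x)
}
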