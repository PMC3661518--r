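#' Lognormal parameters from an arithmetic mean and standard deviation
#'
#' Converts the arithmetic mean and SD of a body-mass-index (BMI)
#' distribution into the `mu`/`sigma` parameters of a lognormal on the BMI
#' scale, by moment matching: `sigma^2 = log(1 + sd^2/mean^2)` and
#' `mu = log(mean) - sigma^2/2`.
#'
#' @param mean Arithmetic mean (BMI units), strictly positive.
#' @param sd Arithmetic standard deviation (BMI units), non-negative. `sd = 0`
#'   degenerates to a point mass (`sigma = 0`, `mu = log(mean)`).
#' @return A list with elements `mu` and `sigma`.
#' @examples
#' p <- lognormal_from_mean_sd(27, 5)
#' exp(p$mu + p$sigma^2 / 2)  # back-transformed mean: 27
#' @export
lognormal_from_mean_sd <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("`mean` must be finite and strictly positive", call. = FALSE)
  if (any(!is.finite(sd)) || any(sd < 0))
    stop("`sd` must be finite and non-negative", call. = FALSE)
  sigma2 <- log1p((sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' BMI exposure distribution partitioned into five categories
#'
#' Builds the exposure object used throughout the risk module: a lognormal
#' BMI distribution (from arithmetic mean/SD) divided into the five standard
#' categories (<25, 25-30, 30-35, 35-40, >40), with the proportion of the
#' population and the truncated-lognormal mean BMI in each category. The
#' truncated mean (not the interval midpoint) is used as each category's
#' representative exposure: it preserves the distribution's mass and is
#' well-defined for the open-ended top category.
#'
#' @param mean,sd Arithmetic mean and SD of BMI (units: kg/m^2).
#' @param cutpoints Category boundaries, default `c(25, 30, 35, 40)`.
#' @return An object of class `bmi_exposure` with fields `mean`, `sd`, `mu`,
#'   `sigma`, `cutpoints`, `p` (proportions, summing to 1) and
#'   `category_mean` (truncated means, strictly increasing).
#' @export
bmi_exposure <- function(mean, sd, cutpoints = c(25, 30, 35, 40)) {
  stopifnot(length(cutpoints) >= 1, !is.unsorted(cutpoints, strictly = TRUE))
  par <- lognormal_from_mean_sd(mean, sd)
  lo <- c(0, cutpoints)
  hi <- c(cutpoints, Inf)
  k <- length(lo)
  if (par$sigma == 0) {
    # Point mass: all weight in the category containing `mean`.
    p <- as.numeric(mean > lo & mean <= hi)
    if (mean <= lo[1]) p[1] <- 1
    m <- .category_fallback_means(lo, hi)
    m[p > 0] <- mean
  } else {
    cdf <- stats::plnorm(hi, par$mu, par$sigma)
    p <- diff(c(0, cdf))
    p[p < 0] <- 0
    m <- .lnorm_truncated_means(par$mu, par$sigma, lo, hi, p)
  }
  structure(
    list(mean = mean, sd = sd, mu = par$mu, sigma = par$sigma,
         cutpoints = cutpoints, p = p, category_mean = m),
    class = "bmi_exposure"
  )
}

# Mean of a lognormal(mu, sigma) truncated to (lo, hi], via the partial
# expectation identity E[X; lo < X <= hi] =
#   exp(mu + sigma^2/2) * (Phi(z_hi - sigma) - Phi(z_lo - sigma)),
# with z = (log(bound) - mu)/sigma. Empty categories fall back to a
# representative interior point so downstream power laws stay finite.
.lnorm_truncated_means <- function(mu, sigma, lo, hi, p) {
  zlo <- ifelse(lo <= 0, -Inf, (log(lo) - mu) / sigma)
  zhi <- ifelse(is.finite(hi), (log(hi) - mu) / sigma, Inf)
  partial <- exp(mu + sigma^2 / 2) *
    (stats::pnorm(zhi - sigma) - stats::pnorm(zlo - sigma))
  m <- ifelse(p > 1e-300, partial / p, NA_real_)
  fb <- .category_fallback_means(lo, hi)
  ifelse(is.finite(m), m, fb)
}

.category_fallback_means <- function(lo, hi) {
  ifelse(is.finite(hi), (lo + hi) / 2, lo + 5)
}

#' @export
print.bmi_exposure <- function(x, ...) {
  cat("BMI exposure: lognormal, arithmetic mean", format(x$mean, digits = 4),
      "SD", format(x$sd, digits = 4), "\n")
  lab <- c(paste0("<", x$cutpoints[1]),
           paste(head2(x$cutpoints), x$cutpoints[-1], sep = "-"),
           paste0(">", x$cutpoints[length(x$cutpoints)]))
  out <- data.frame(category = lab, proportion = round(x$p, 4),
                    mean_bmi = round(x$category_mean, 2))
  print(out, row.names = FALSE)
  invisible(x)
}

head2 <- function(x) x[-length(x)]

#' Category proportions of a BMI exposure
#'
#' Proportion of the population in each BMI category, i.e. the lognormal
#' integral between successive cutpoints. Sums to 1 by construction.
#'
#' @param exposure A [bmi_exposure()] object.
#' @return Numeric vector of proportions, one per category.
#' @export
category_proportions <- function(exposure) {
  stopifnot(inherits(exposure, "bmi_exposure"))
  exposure$p
}

#' Category relative risks from a per-unit relative risk
#'
#' Expands a relative risk per 1 BMI unit into category-level relative risks
#' via the power relationship `RR_i = rr_unit^(m_i - m_1)`, where `m_i` is
#' the truncated-lognormal mean BMI of category `i` and category 1 is the
#' reference (so `RR_1 = 1` exactly).
#'
#' @param rr_unit Relative risk per BMI unit, `>= 1` (protective exposures
#'   are out of scope).
#' @param exposure A [bmi_exposure()] object.
#' @return Numeric vector of category relative risks, non-decreasing, first
#'   element 1.
#' @export
category_relative_risks <- function(rr_unit, exposure) {
  stopifnot(inherits(exposure, "bmi_exposure"))
  if (!is.finite(rr_unit) || rr_unit < 1)
    stop("`rr_unit` must be >= 1 (protective exposures not supported)",
         call. = FALSE)
  m <- exposure$category_mean
  rr_unit^(m - m[1])
}

#' Shift category relative risks for an exposure reduction
#'
#' Applies a BMI reduction of `delta_bmi` units to the eligible categories:
#' `RR'_i = max(1, RR_i * rr_unit^(-delta_bmi))` for eligible `i`, unchanged
#' otherwise. Category prevalences are held constant; only the risk attached
#' to treated categories moves. The floor at 1 encodes that a treated person
#' cannot drop below reference risk.
#'
#' @param rr Vector of category relative risks (from
#'   [category_relative_risks()]).
#' @param rr_unit Relative risk per BMI unit used to build `rr`.
#' @param delta_bmi BMI-unit reduction, `>= 0`.
#' @param eligible Integer indices of the categories receiving the
#'   intervention (e.g. `5` for the BMI>40 scenario, `4:5` for BMI>35).
#' @return Vector of shifted relative risks `RR'`.
#' @export
shift_relative_risks <- function(rr, rr_unit, delta_bmi, eligible) {
  stopifnot(all(rr >= 1), rr_unit >= 1, delta_bmi >= 0)
  stopifnot(all(eligible %in% seq_along(rr)))
  out <- rr
  out[eligible] <- pmax(1, rr[eligible] * rr_unit^(-delta_bmi))
  out
}

#' Potential impact fraction
#'
#' The proportional change in average disease incidence after a change in
#' risk-factor exposure:
#' `PIF = (sum(p * RR) - sum(p * RR')) / sum(p * RR)`.
#'
#' @param p Category proportions (must sum to 1).
#' @param rr Pre-intervention category relative risks.
#' @param rr_shifted Post-intervention category relative risks
#'   (`RR'_i <= RR_i`).
#' @return The PIF, a scalar in `[0, 1)`.
#' @examples
#' potential_impact_fraction(c(0.8, 0.2), c(1, 2), c(1, 1.5))  # 1/12
#' @export
potential_impact_fraction <- function(p, rr, rr_shifted) {
  stopifnot(length(p) == length(rr), length(rr) == length(rr_shifted))
  if (abs(sum(p) - 1) > 1e-8)
    stop("category proportions must sum to 1", call. = FALSE)
  if (any(rr_shifted > rr + 1e-12))
    stop("shifted relative risks must not exceed baseline", call. = FALSE)
  denom <- sum(p * rr)
  if (denom <= 0) stop("sum(p * RR) must be positive", call. = FALSE)
  (denom - sum(p * rr_shifted)) / denom
}

#' Adjust a disease incidence rate by a potential impact fraction
#'
#' `I' = I * (1 - PIF)`.
#'
#' @param incidence Incidence rate(s), `>= 0` (events per person-year).
#' @param pif Potential impact fraction(s) in `[0, 1)`.
#' @return Adjusted incidence, same shape as `incidence`.
#' @export
adjust_incidence <- function(incidence, pif) {
  stopifnot(all(incidence >= 0), all(pif >= 0), all(pif < 1))
  incidence * (1 - pif)
}

#' Apply a secular BMI trend to an exposure distribution
#'
#' Shifts the arithmetic mean upwards by `annual_increment` BMI units per
#' year elapsed, capped at `horizon_years` (the trend is projected a fixed
#' number of years into the future and held constant thereafter, for both
#' intervention and reference populations). The SD is unchanged; the
#' lognormal parameters are re-derived from the shifted mean.
#'
#' @param exposure A [bmi_exposure()] object.
#' @param years_elapsed Years since baseline, `>= 0`.
#' @param annual_increment Trend, BMI units per calendar year.
#' @param horizon_years Cap on the trend, default 20 years.
#' @return A new `bmi_exposure` object.
#' @export
apply_bmi_trend <- function(exposure, years_elapsed, annual_increment,
                            horizon_years = 20) {
  stopifnot(inherits(exposure, "bmi_exposure"), years_elapsed >= 0)
  shift <- annual_increment * min(years_elapsed, horizon_years)
  if (shift == 0) return(exposure)
  bmi_exposure(exposure$mean + shift, exposure$sd, exposure$cutpoints)
}
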