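# Independent oracles used to check the implementation. These deliberately
# avoid the package's own computational paths: quadrature instead of closed
# forms, explicit matrix powers instead of the vectorised recursion, a
# scratch loop instead of the life-table code.

# Mean of a lognormal truncated to (lo, hi], by adaptive quadrature.
oracle_truncated_mean <- function(mu, sigma, lo, hi) {
  num <- stats::integrate(function(x) x * stats::dlnorm(x, mu, sigma),
                          lo, hi, rel.tol = 1e-12)$value
  den <- stats::integrate(function(x) stats::dlnorm(x, mu, sigma),
                          lo, hi, rel.tol = 1e-12)$value
  num / den
}

# Category proportions by quadrature of the lognormal density.
oracle_category_proportions <- function(mu, sigma,
                                        cutpoints = c(25, 30, 35, 40)) {
  lo <- c(0, cutpoints)
  hi <- c(cutpoints, Inf)
  vapply(seq_along(lo), function(i)
    stats::integrate(function(x) stats::dlnorm(x, mu, sigma),
                     lo[i], hi[i], rel.tol = 1e-12)$value, 1.0)
}

# Continuous potential impact fraction: quadrature over the lognormal
# density with RR(b) = rr^(b - m1), exposure shifted by delta BMI units for
# b above the eligibility cutoff, floored at 1. The integral over the full
# support diverges for rr > 1 (exponential growth beats lognormal decay),
# so the domain is truncated at a physiological ceiling of BMI 100.
oracle_continuous_pif <- function(mean, sd, rr_unit, delta_bmi, cutoff,
                                  upper = 100) {
  par <- lognormal_from_mean_sd(mean, sd)
  m1 <- oracle_truncated_mean(par$mu, par$sigma, 0, 25)
  f <- function(b) stats::dlnorm(b, par$mu, par$sigma) * rr_unit^(b - m1)
  fs <- function(b) stats::dlnorm(b, par$mu, par$sigma) *
    ifelse(b > cutoff, pmax(1, rr_unit^(b - m1 - delta_bmi)),
           rr_unit^(b - m1))
  A <- stats::integrate(f, 0, upper, rel.tol = 1e-10)$value
  B <- stats::integrate(fs, 0, upper, rel.tol = 1e-10)$value
  (A - B) / A
}

# Categorical PIF assembled from the package's public operations (the path
# under test, kept here so acceptance and unit tests share it).
categorical_pif <- function(mean, sd, rr_unit, delta_bmi, scenario) {
  ex <- bmi_exposure(mean, sd)
  rr <- category_relative_risks(rr_unit, ex)
  rrs <- shift_relative_risks(rr, rr_unit, delta_bmi,
                              eligible_categories(scenario))
  potential_impact_fraction(ex$p, rr, rrs)
}

# Disease life table under constant rates via explicit powers of the 2x2
# transition matrix on (S, C).
oracle_disease_constant <- function(i, f, r, steps, S0, C0) {
  Pi <- 1 - exp(-i); Pf <- 1 - exp(-f); Pr <- 1 - exp(-r)
  M <- matrix(c(1 - Pi, Pi, Pr, 1 - Pf - Pr), 2, 2)
  state <- c(S0, C0)
  out <- matrix(0, steps, 2)
  out[1, ] <- state
  for (k in seq_len(steps - 1L)) {
    state <- M %*% state
    out[k + 1L, ] <- state
  }
  data.frame(S = out[, 1], C = out[, 2],
             prevalence = ifelse(rowSums(out) > 0, out[, 2] / rowSums(out), 0))
}

# Individual-level microsimulation through the same annual transition
# probabilities; states 1 = well, 2 = diseased, 3 = dead of disease.
oracle_disease_microsim <- function(epi, n_individuals, p_init, seed) {
  set.seed(seed)
  Pi <- 1 - exp(-epi$incidence)
  Pf <- 1 - exp(-epi$case_fatality)
  Pr <- 1 - exp(-epi$remission)
  n_ages <- length(epi$ages)
  state <- ifelse(stats::runif(n_individuals) < p_init, 2L, 1L)
  prev <- numeric(n_ages)
  alive_n <- integer(n_ages)
  for (k in seq_len(n_ages)) {
    alive <- state != 3L
    prev[k] <- sum(state == 2L) / sum(alive)
    alive_n[k] <- sum(alive)
    if (k == n_ages) break
    u <- stats::runif(n_individuals)
    well <- state == 1L
    sick <- state == 2L
    new_state <- state
    new_state[well & u < Pi[k]] <- 2L
    new_state[sick & u < Pf[k]] <- 3L
    new_state[sick & u >= Pf[k] & u < Pf[k] + Pr[k]] <- 1L
    state <- new_state
  }
  list(prevalence = prev, alive = alive_n)
}

# Spreadsheet-style life table: scalar loop with running accumulators,
# written independently of run_master_lifetable().
oracle_lifetable_loop <- function(m, w, start_age, cohort = 1, extra = 0) {
  n <- length(m)
  extra <- rep_len(extra, n)
  l <- cohort; lvec <- numeric(n); Lvec <- numeric(n); Lwvec <- numeric(n)
  for (k in seq_len(n)) {
    lvec[k] <- l
    q <- 1 - exp(-m[k]) * (1 - extra[k])
    l_next <- if (k == n) 0 else l * (1 - q)
    Lvec[k] <- (l + l_next) / 2
    Lwvec[k] <- Lvec[k] * (1 - w[k])
    l <- l_next
  }
  data.frame(age = start_age + seq_len(n) - 1L, l = lvec, L = Lvec,
             Lw = Lwvec)
}
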