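#' Per-disease epidemiology container
#'
#' Bundles the per-age rates driving one disease's illness-death life table:
#' incidence, case fatality among prevalent cases, remission, plus the
#' disability weight and whether the disease is costed per incident case
#' (the cancer convention) or per prevalent case-year.
#'
#' @param id Disease identifier (character).
#' @param incidence,case_fatality,remission Numeric vectors of rates per
#'   person-year, one value per age in `ages`. `remission` defaults to zero
#'   (chronic diseases).
#' @param disability_weight Scalar in (0, 1).
#' @param cancer Logical; `TRUE` flags incident-case costing.
#' @param ages Integer ages the rates refer to, default `20:100`.
#' @return An object of class `disease_epidemiology`.
#' @export
disease_epidemiology <- function(id, incidence, case_fatality,
                                 remission = NULL, disability_weight,
                                 cancer = FALSE, ages = 20:100) {
  n <- length(ages)
  if (is.null(remission)) remission <- rep(0, n)
  if (length(incidence) == 1L) incidence <- rep(incidence, n)
  if (length(case_fatality) == 1L) case_fatality <- rep(case_fatality, n)
  if (length(remission) == 1L) remission <- rep(remission, n)
  stopifnot(length(incidence) == n, length(case_fatality) == n,
            length(remission) == n)
  if (any(incidence < 0) || any(case_fatality < 0) || any(remission < 0))
    stop("disease rates must be non-negative", call. = FALSE)
  if (!is.numeric(disability_weight) || disability_weight <= 0 ||
      disability_weight >= 1)
    stop("`disability_weight` must lie in (0, 1)", call. = FALSE)
  structure(
    list(id = id, ages = ages, incidence = incidence,
         case_fatality = case_fatality, remission = remission,
         disability_weight = disability_weight, cancer = isTRUE(cancer)),
    class = "disease_epidemiology"
  )
}

# Shared annual recursion on conditional (alive-from-other-causes) state
# fractions. Pi, Pf, Pr are probability matrices (ages x K trajectories);
# S0, C0 initial fractions. Returns S, C matrices of the same shape.
.disease_recursion <- function(Pi, Pf, Pr, S0, C0) {
  n <- nrow(Pi)
  K <- ncol(Pi)
  S <- matrix(0, n, K)
  C <- matrix(0, n, K)
  S[1, ] <- S0
  C[1, ] <- C0
  for (k in seq_len(n - 1L)) {
    S[k + 1L, ] <- S[k, ] * (1 - Pi[k, ]) + C[k, ] * Pr[k, ]
    C[k + 1L, ] <- C[k, ] * (1 - Pf[k, ] - Pr[k, ]) + S[k, ] * Pi[k, ]
  }
  list(S = S, C = C)
}

# Burn-in from age 0 at constant young-adult rates to seed prevalence at the
# first modelled age.
.burnin_init <- function(i0, f0, r0, years = 20L) {
  Pi <- 1 - exp(-i0); Pf <- 1 - exp(-f0); Pr <- 1 - exp(-r0)
  S <- rep(1, length(i0)); C <- rep(0, length(i0))
  for (k in seq_len(years)) {
    S_new <- S * (1 - Pi) + C * Pr
    C_new <- C * (1 - Pf - Pr) + S * Pi
    S <- S_new; C <- C_new
  }
  list(S = S, C = C)
}

#' Run a three-state disease life table
#'
#' Propagates one disease through the well -> diseased -> dead-of-disease
#' states by annual steps, conditional on survival from all other causes
#' (the proportional life-table assumption: other-cause death is handled
#' solely in the master table). Rates are converted to annual probabilities
#' by `P = 1 - exp(-rate)` and the recursion is
#' `S_{x+1} = S_x (1 - P_i) + C_x P_r`;
#' `C_{x+1} = C_x (1 - P_f - P_r) + S_x P_i`.
#'
#' The starting prevalence at the first age is obtained by a burn-in from
#' age 0 at constant young-adult (first-age) rates, unless `p_init` is given
#' explicitly.
#'
#' @param epi A [disease_epidemiology()] object.
#' @param incidence_override Optional per-age incidence replacing
#'   `epi$incidence` (e.g. post-intervention incidence `I * (1 - PIF)`).
#'   The burn-in always uses baseline incidence, so overridden runs start
#'   from the same initial prevalence.
#' @param p_init Optional explicit prevalence at the first age.
#' @return A data.frame of class `disease_trajectory` with columns `age`,
#'   `S`, `C`, `prevalence`, `mortality` (`f_x * p_x`) and `pyld`
#'   (`p_x * w_d`); the epidemiology is attached as attribute `epi`.
#' @export
run_disease_lifetable <- function(epi, incidence_override = NULL,
                                  p_init = NULL) {
  stopifnot(inherits(epi, "disease_epidemiology"))
  inc <- if (is.null(incidence_override)) epi$incidence else incidence_override
  if (length(inc) != length(epi$ages))
    stop("`incidence_override` must have one rate per age", call. = FALSE)
  if (any(inc < 0)) stop("incidence must be non-negative", call. = FALSE)

  Pf <- 1 - exp(-epi$case_fatality)
  Pr <- 1 - exp(-epi$remission)
  bad <- which(Pf + Pr > 1)
  if (length(bad))
    stop(sprintf(
      "case-fatality and remission probabilities exceed 1 at age %d",
      epi$ages[bad[1]]), call. = FALSE)
  Pi <- 1 - exp(-inc)

  if (is.null(p_init)) {
    init <- .burnin_init(epi$incidence[1], epi$case_fatality[1],
                         epi$remission[1], years = epi$ages[1])
  } else {
    stopifnot(p_init >= 0, p_init <= 1)
    init <- list(S = 1 - p_init, C = p_init)
  }

  st <- .disease_recursion(cbind(Pi), cbind(Pf), cbind(Pr), init$S, init$C)
  S <- st$S[, 1]; C <- st$C[, 1]
  alive <- S + C
  prev <- ifelse(alive > 0, C / alive, 0)
  out <- data.frame(
    age = epi$ages, S = S, C = C, prevalence = prev,
    mortality = epi$case_fatality * prev,
    pyld = prev * epi$disability_weight
  )
  attr(out, "epi") <- epi
  class(out) <- c("disease_trajectory", class(out))
  out
}

#' Disease-specific mortality and disability-adjusted prevalence
#'
#' Extracts the per-age terms a trajectory contributes to the master life
#' table: the disease mortality rate `m_d = f_x * p_x` and the
#' disability-adjusted prevalence `pYLD_d = p_x * w_d`.
#'
#' @param traj A `disease_trajectory` from [run_disease_lifetable()].
#' @return A list with numeric vectors `mortality` and `pyld`.
#' @export
disease_mortality_and_pyld <- function(traj) {
  stopifnot(inherits(traj, "disease_trajectory"))
  list(mortality = traj$mortality, pyld = traj$pyld)
}
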