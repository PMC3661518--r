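#' Mortality and disability from all other causes
#'
#' The proportional multi-state life table converts all-cause rates into
#' "all other causes" rates by subtracting the modelled diseases'
#' pre-intervention contributions: `m- = m+ - sum_d m_d` and
#' `w- = w+ - sum_d pYLD_d` at every age.
#'
#' @param m_all,w_all All-cause mortality rate and total pYLD rate per age.
#' @param m_disease,pyld_disease Per-disease terms: matrices (ages x
#'   diseases) or vectors for a single disease.
#' @param ages Optional ages, used in error messages only.
#' @return A list with vectors `m_other` and `w_other`.
#' @export
decompose_other_causes <- function(m_all, w_all, m_disease, pyld_disease,
                                   ages = seq_along(m_all) + 19L) {
  m_disease <- cbind(m_disease)
  pyld_disease <- cbind(pyld_disease)
  stopifnot(nrow(m_disease) == length(m_all),
            nrow(pyld_disease) == length(w_all))
  m_other <- m_all - rowSums(m_disease)
  w_other <- w_all - rowSums(pyld_disease)
  if (any(m_other < 0)) {
    a <- ages[which(m_other < 0)[1]]
    stop(sprintf(
      "disease mortality exceeds all-cause mortality at age %d", a),
      call. = FALSE)
  }
  if (any(w_other < 0)) {
    a <- ages[which(w_other < 0)[1]]
    stop(sprintf("disease pYLD exceeds total pYLD at age %d", a),
         call. = FALSE)
  }
  list(m_other = m_other, w_other = w_other)
}

#' Recompose total mortality and disability after intervention
#'
#' Adds revised (post-intervention) disease-specific terms back onto the
#' all-other-cause residuals: `m+' = m- + sum_d m'_d`,
#' `w+' = w- + sum_d pYLD'_d`. With unchanged disease terms this is the
#' exact inverse of [decompose_other_causes()].
#'
#' @param m_other,w_other Residual rates from [decompose_other_causes()].
#' @param m_disease,pyld_disease Revised per-disease terms (matrices or
#'   vectors as in [decompose_other_causes()]).
#' @return A list with vectors `m_total` and `w_total`.
#' @export
recompose_total <- function(m_other, w_other, m_disease, pyld_disease) {
  m_disease <- cbind(m_disease)
  pyld_disease <- cbind(pyld_disease)
  stopifnot(nrow(m_disease) == length(m_other),
            nrow(pyld_disease) == length(w_other))
  list(m_total = m_other + rowSums(m_disease),
       w_total = w_other + rowSums(pyld_disease))
}

#' Run the master cohort life table
#'
#' Simulates a closed cohort from `start_age` until everyone has died or
#' reached age 100, using standard abridged life-table conventions:
#' `q_x = 1 - exp(-m_x)`, combined multiplicatively with any extra
#' (surgical) mortality as an independent competing risk;
#' `l_{x+1} = l_x (1 - q_x)`; half-cycle life years
#' `L_x = (l_x + l_{x+1}) / 2`; disability-adjusted life years
#' `Lw_x = L_x (1 - w_x)`; life expectancy `e_x` and disability-adjusted
#' life expectancy `DALE_x` as tail sums of `L` and `Lw` divided by `l_x`.
#' The table closes at 100 (`l_101 = 0`).
#'
#' @param mortality Total mortality rate per age (`start_age:100`).
#' @param pyld_rate Total pYLD rate per age (same length).
#' @param start_age First age of the cohort.
#' @param cohort_size Persons at `start_age` (default 1).
#' @param extra_mortality Per-age additional annual death probability (e.g.
#'   surgical mortality in the first two post-operative years); scalar or
#'   vector, default 0.
#' @return An object of class `cohort_lifetable`: a data.frame with columns
#'   `age`, `m`, `w`, `q`, `l`, `L`, `Lw`, `e`, `DALE`, with attributes
#'   `start_age`, `cohort_size`, `total_L`, `total_Lw`.
#' @export
run_master_lifetable <- function(mortality, pyld_rate, start_age,
                                 cohort_size = 1, extra_mortality = 0) {
  ages <- start_age:100
  n <- length(ages)
  stopifnot(length(mortality) == n, length(pyld_rate) == n)
  if (any(mortality < 0) || any(pyld_rate < 0) || any(pyld_rate >= 1))
    stop("rates out of range: mortality >= 0, pYLD in [0, 1) required",
         call. = FALSE)
  extra <- rep_len(extra_mortality, n)
  stopifnot(all(extra >= 0), all(extra <= 1))
  q <- 1 - (1 - (1 - exp(-mortality))) * (1 - extra)
  l <- numeric(n + 1L)
  l[1] <- cohort_size
  for (k in seq_len(n)) l[k + 1L] <- l[k] * (1 - q[k])
  l[n + 1L] <- 0  # closure: nobody lives past 100
  L <- (l[seq_len(n)] + l[-1L]) / 2
  Lw <- L * (1 - pyld_rate)
  tailL <- rev(cumsum(rev(L)))
  tailLw <- rev(cumsum(rev(Lw)))
  lx <- l[seq_len(n)]
  e <- ifelse(lx > 0, tailL / lx, 0)
  DALE <- ifelse(lx > 0, tailLw / lx, 0)
  out <- data.frame(age = ages, m = mortality, w = pyld_rate, q = q,
                    l = lx, L = L, Lw = Lw, e = e, DALE = DALE)
  attr(out, "start_age") <- start_age
  attr(out, "cohort_size") <- cohort_size
  attr(out, "total_L") <- sum(L)
  attr(out, "total_Lw") <- sum(Lw)
  class(out) <- c("cohort_lifetable", class(out))
  out
}

#' DALYs averted between two cohort life tables
#'
#' Discounted difference in disability-adjusted life years between an
#' intervention and a reference cohort (or matched lists of cohorts, e.g.
#' one per age-sex stratum). Discounting is annual-discrete and end-of-year:
#' the cohort's `t`-th year (`t = 1` for the year starting at
#' `start_age`) is weighted `(1 + rate)^-t`.
#'
#' @param reference,intervention `cohort_lifetable` objects, or lists of
#'   them with matching strata.
#' @param discount_rate Annual discount rate, default 0.03.
#' @return DALYs averted (person-years), positive when the intervention arm
#'   accrues more healthy life.
#' @export
dalys_averted <- function(reference, intervention, discount_rate = 0.03) {
  if (inherits(reference, "cohort_lifetable"))
    reference <- list(reference)
  if (inherits(intervention, "cohort_lifetable"))
    intervention <- list(intervention)
  if (length(reference) != length(intervention))
    stop("reference and intervention arms must have the same strata",
         call. = FALSE)
  total <- 0
  for (i in seq_along(reference)) {
    r <- reference[[i]]; v <- intervention[[i]]
    if (!identical(r$age, v$age))
      stop("mismatched ages between arms in stratum ", i, call. = FALSE)
    t <- r$age - attr(r, "start_age") + 1
    total <- total + sum((v$Lw - r$Lw) * (1 + discount_rate)^(-t))
  }
  total
}
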