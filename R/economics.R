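#' Intervention cost set
#'
#' Per-person costs of the LAGB intervention (2003 AU$): the initial surgery
#' cost (which bundles two years of post-operative follow-up and is booked
#' entirely at the year of surgery), and the annual maintenance and
#' complication costs applied to surviving recipients from year three
#' onwards. The `"time_travel"` variant additionally prices patients' time
#' and travel.
#'
#' @param variant `"baseline"` (surgery 11290, maintenance 330,
#'   complications 90) or `"time_travel"` (12452, 1126, 105).
#' @param surgery,maintenance,complications Optional overrides (AU$/person).
#' @return An object of class `cost_set`.
#' @export
cost_set <- function(variant = c("baseline", "time_travel"),
                     surgery = NULL, maintenance = NULL,
                     complications = NULL) {
  variant <- match.arg(variant)
  defaults <- switch(variant,
    baseline    = c(surgery = 11290, maintenance = 330, complications = 90),
    time_travel = c(surgery = 12452, maintenance = 1126, complications = 105))
  out <- list(
    variant = variant,
    surgery = if (is.null(surgery)) defaults[["surgery"]] else surgery,
    maintenance = if (is.null(maintenance)) defaults[["maintenance"]]
                  else maintenance,
    complications = if (is.null(complications)) defaults[["complications"]]
                    else complications)
  if (any(unlist(out[-1]) < 0)) stop("costs must be >= 0", call. = FALSE)
  class(out) <- "cost_set"
  out
}

#' Discount a value to present terms
#'
#' @param value Amount (AU$ or person-years).
#' @param rate Annual discount rate, `>= 0`.
#' @param t_years Years from the reference year (vectorised).
#' @return `value / (1 + rate)^t_years`.
#' @export
discount <- function(value, rate, t_years) {
  stopifnot(rate >= 0, all(t_years >= 0))
  value / (1 + rate)^t_years
}

#' Intervention costs for an operated cohort
#'
#' The initial surgery cost is applied once, at the year of surgery, to every
#' person operated on. The aggregate annual maintenance-plus-complication
#' cost is applied to surviving recipients from post-operative year 3 to
#' death or age 100, discounted back to the surgery year.
#'
#' @param n_operated Persons receiving surgery (scalar or per-stratum
#'   vector).
#' @param person_years Person-years lived by the operated subset, indexed by
#'   year since surgery starting at year 1: a vector, or a matrix with one
#'   row per year and one column per stratum.
#' @param costs A [cost_set()].
#' @param rate Discount rate, default 0.03.
#' @param complication_multiplier Scaling of the complication component
#'   (e.g. 10 for the higher-complications sensitivity analysis).
#' @param maintenance_start_year First year carrying maintenance and
#'   complication costs, default 3.
#' @return List with `initial`, `maintenance` (both AU$) and `total`.
#' @export
intervention_costs <- function(n_operated, person_years, costs, rate = 0.03,
                               complication_multiplier = 1,
                               maintenance_start_year = 3) {
  stopifnot(inherits(costs, "cost_set"), all(n_operated >= 0),
            complication_multiplier >= 0)
  py <- cbind(person_years)
  years <- seq_len(nrow(py))            # year since surgery, 1-based
  annual <- costs$maintenance + costs$complications * complication_multiplier
  weight <- ifelse(years >= maintenance_start_year, (1 + rate)^(-years), 0)
  initial <- sum(n_operated) * costs$surgery
  maintenance <- annual * sum(py * weight)
  list(initial = initial, maintenance = maintenance,
       total = initial + maintenance)
}

#' Disease cost offsets between arms
#'
#' Health-care costs avoided through reduced disease after intervention.
#' Chronic diseases are costed per prevalent case-year averted; cancers per
#' incident case averted (prevalence is hard to define and costs cluster
#' around the incident event). The result is reported as a negative number
#' (a saving) whenever the intervention reduces disease.
#'
#' @param reference,intervention Lists with matrices `prevalent_py` and
#'   `incident_cases` (years since start x diseases), columns named by
#'   disease.
#' @param unit_costs Data frame with columns `disease`, `cancer` (logical)
#'   and `unit_cost` (AU$ per prevalent case-year, or per incident case for
#'   cancers).
#' @param rate Discount rate, default 0.03.
#' @return Total cost offset (AU$, negative = saving).
#' @export
cost_offsets <- function(reference, intervention, unit_costs, rate = 0.03) {
  dref <- colnames(reference$prevalent_py)
  dint <- colnames(intervention$prevalent_py)
  if (!identical(sort(dref), sort(dint)) ||
      !setequal(dref, unit_costs$disease))
    stop("disease sets do not match between arms and unit costs",
         call. = FALSE)
  t <- seq_len(nrow(reference$prevalent_py))   # end-of-year discounting
  disc <- (1 + rate)^(-t)
  total <- 0
  for (j in seq_len(nrow(unit_costs))) {
    d <- unit_costs$disease[j]
    if (isTRUE(unit_costs$cancer[j])) {
      averted <- reference$incident_cases[, d] - intervention$incident_cases[, d]
    } else {
      averted <- reference$prevalent_py[, d] - intervention$prevalent_py[, d]
    }
    total <- total + sum(averted * disc) * unit_costs$unit_cost[j]
  }
  -total
}

#' Costs of unrelated diseases in added years of life
#'
#' Life extension brings health-care costs for conditions unrelated to the
#' intervention. Applied only in the costing scenario that includes them.
#'
#' @param extra_life_years Incremental life-years (intervention minus
#'   reference) per year since start.
#' @param unit_cost Annual unrelated-disease cost per life-year for the same
#'   years (scalar or vector, already resolved for age and sex).
#' @param rate Discount rate, default 0.03.
#' @return Total unrelated-disease cost (AU$).
#' @export
unrelated_disease_costs <- function(extra_life_years, unit_cost,
                                    rate = 0.03) {
  n <- length(extra_life_years)
  cost <- rep_len(unit_cost, n)
  t <- seq_len(n)                               # end-of-year discounting
  sum(extra_life_years * cost * (1 + rate)^(-t))
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param net_cost Net cost (AU$; may be negative).
#' @param dalys DALYs averted.
#' @return An object of class `icer`: list with `value` (AU$/DALY or `NA`
#'   when labelled) and `label` (`"dominant"` when the intervention saves
#'   money and improves health, `"dominated"` when it costs more and harms
#'   health, otherwise `NA`).
#' @export
icer <- function(net_cost, dalys) {
  if (dalys == 0 && net_cost != 0) {
    warning("DALYs averted is zero with non-zero net cost: ICER undefined")
    out <- list(value = NA_real_, label = NA_character_)
  } else if (net_cost < 0 && dalys > 0) {
    out <- list(value = NA_real_, label = "dominant")
  } else if (net_cost > 0 && dalys < 0) {
    out <- list(value = NA_real_, label = "dominated")
  } else if (dalys == 0) {
    out <- list(value = 0, label = NA_character_)
  } else {
    out <- list(value = net_cost / dalys, label = NA_character_)
  }
  structure(out, class = "icer")
}

#' @export
format.icer <- function(x, ...) {
  if (!is.na(x$label)) return(x$label)
  paste0("$", format(round(x$value), big.mark = " "), "/DALY")
}

#' @export
print.icer <- function(x, ...) {
  cat("ICER:", format(x), "\n")
  invisible(x)
}

#' Budget impact of funding surgery for the eligible population
#'
#' First-year fiscal cost of operating on every eligible person, and its
#' share of government health expenditure.
#'
#' @param eligible_count Number of eligible persons.
#' @param cost_per_person Surgery cost per person (AU$).
#' @param govt_expenditure Government health expenditure (same units as the
#'   product, typically AU$).
#' @return List with `total` (AU$), `total_millions` and `percent` (of
#'   expenditure).
#' @export
budget_impact <- function(eligible_count, cost_per_person,
                          govt_expenditure) {
  stopifnot(eligible_count >= 0, cost_per_person > 0, govt_expenditure > 0)
  total <- eligible_count * cost_per_person
  list(total = total, total_millions = total / 1e6,
       percent = 100 * total / govt_expenditure)
}
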