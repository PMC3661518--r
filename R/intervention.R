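#' Specification of the gastric-banding intervention
#'
#' Collects the effectiveness and safety parameters of laparoscopic
#' adjustable gastric banding (LAGB) as delivered to all eligible members of
#' a population: the weight-loss trajectory (0 kg at surgery, 27.4 kg at two
#' years, a stable peak of 32.0 kg from year three), post-operative
#' mortality (first year and second year only; zero from year three), and
#' annual long-term complication risks applying from year three onwards.
#'
#' @param scenario `"bmi40"` (surgery for everyone with BMI > 40) or
#'   `"bmi35"` (extended to BMI > 35).
#' @param peak_loss_kg Stable weight loss from year 3 (kg), default 32.0.
#' @param two_year_loss_kg Weight loss at year 2 (kg), default 27.4.
#' @param mortality_first_year Post-surgical death probability applied to
#'   the first year (the <30-day risk), default 0.0006.
#' @param mortality_second_year Death probability applied to the second
#'   year (30 days to 2 years), default 0.
#' @param complication_risks Named annual risks per person-year from year 3:
#'   gastric prolapse, band erosion, port infection, band removal.
#' @param kg_per_bmi_unit Conversion between kg lost and BMI units lost,
#'   default 3.2 (30 kg is roughly 10 BMI units in this population).
#' @param annual_attenuation Fractional decay of the peak loss per year over
#'   years 3-15 when the attenuation sensitivity analysis is switched on;
#'   default 0.007/year.
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(scenario = c("bmi40", "bmi35"),
                              peak_loss_kg = 32.0,
                              two_year_loss_kg = 27.4,
                              mortality_first_year = 0.0006,
                              mortality_second_year = 0.0,
                              complication_risks = c(gastric_prolapse = 0.01,
                                                     band_erosion = 0.001,
                                                     port_infection = 0.002,
                                                     band_removal = 0.004),
                              kg_per_bmi_unit = 3.2,
                              annual_attenuation = 0.007) {
  scenario <- match.arg(scenario)
  stopifnot(peak_loss_kg >= two_year_loss_kg, two_year_loss_kg >= 0,
            mortality_first_year >= 0, mortality_first_year <= 1,
            mortality_second_year >= 0, mortality_second_year <= 1,
            all(complication_risks >= 0), all(complication_risks <= 1),
            kg_per_bmi_unit > 0,
            annual_attenuation >= 0, annual_attenuation < 1)
  structure(
    list(scenario = scenario, peak_loss_kg = peak_loss_kg,
         two_year_loss_kg = two_year_loss_kg,
         mortality_first_year = mortality_first_year,
         mortality_second_year = mortality_second_year,
         complication_risks = complication_risks,
         kg_per_bmi_unit = kg_per_bmi_unit,
         annual_attenuation = annual_attenuation),
    class = "intervention_spec"
  )
}

#' Weight loss at a given time since surgery
#'
#' Piecewise-linear trajectory: 0 kg at surgery, `two_year_loss_kg` at two
#' years, `peak_loss_kg` at three years, constant thereafter.
#'
#' @param t Years since surgery (vectorised), `>= 0`.
#' @param spec An [intervention_spec()].
#' @return Weight loss in kg, same length as `t`.
#' @export
weight_loss_at <- function(t, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  w2 <- spec$two_year_loss_kg
  wp <- spec$peak_loss_kg
  ifelse(t <= 2, t / 2 * w2,
         ifelse(t <= 3, w2 + (t - 2) * (wp - w2), wp))
}

#' Weight loss with long-run attenuation
#'
#' Sensitivity-analysis variant: identical to [weight_loss_at()] up to year
#' 3, then the peak loss decays geometrically by `annual_attenuation` per
#' year until year 15, and stays constant afterwards.
#'
#' @inheritParams weight_loss_at
#' @param annual_attenuation Fractional decay per year in `[0, 1)`; defaults
#'   to the value stored in `spec`.
#' @return Weight loss in kg.
#' @export
attenuated_weight_loss_at <- function(t, spec,
                                      annual_attenuation = spec$annual_attenuation) {
  stopifnot(annual_attenuation >= 0, annual_attenuation < 1)
  base <- weight_loss_at(t, spec)
  decay_years <- pmax(0, pmin(t, 15) - 3)
  ifelse(t <= 3, base, spec$peak_loss_kg * (1 - annual_attenuation)^decay_years)
}

#' Surgical mortality for a post-operative year
#'
#' Year 1 carries the <30-day mortality risk, year 2 the 30-day-to-2-year
#' risk, and from year 3 onwards post-surgical mortality is zero.
#'
#' @param year_since_surgery Year index (1 = first year after surgery).
#' @param spec An [intervention_spec()].
#' @return Annual death probability attributable to surgery.
#' @export
surgical_mortality_for_year <- function(year_since_surgery, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  if (any(year_since_surgery < 1))
    stop("`year_since_surgery` starts at 1", call. = FALSE)
  ifelse(year_since_surgery == 1, spec$mortality_first_year,
         ifelse(year_since_surgery == 2, spec$mortality_second_year, 0))
}

#' Fraction of a stratum eligible for surgery
#'
#' The proportion of the BMI distribution above the scenario threshold:
#' category 5 (>40) for the BMI>40 scenario, categories 4-5 (>35) for the
#' BMI>35 scenario.
#'
#' @param exposure A [bmi_exposure()] object.
#' @param scenario `"bmi40"` or `"bmi35"`.
#' @return Proportion in `[0, 1]`.
#' @export
eligible_fraction <- function(exposure, scenario = c("bmi40", "bmi35")) {
  scenario <- match.arg(scenario)
  p <- category_proportions(exposure)
  if (scenario == "bmi40") p[5] else p[4] + p[5]
}

#' Categories receiving surgery under a scenario
#'
#' @param scenario `"bmi40"` or `"bmi35"`.
#' @return Integer indices into the five BMI categories.
#' @export
eligible_categories <- function(scenario = c("bmi40", "bmi35")) {
  scenario <- match.arg(scenario)
  if (scenario == "bmi40") 5L else 4:5
}
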