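---
title: "A proportional multi-state life table model for bariatric surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A proportional multi-state life table model for bariatric surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmslt)
```

## The model

`pmslt` evaluates a population-level weight-loss intervention --
laparoscopic adjustable gastric banding (LAGB) offered to every adult above
a BMI eligibility threshold -- with a proportional multi-state life table.
The population is partitioned into 5-year age by sex cohorts (ages 20-95,
32 strata), each simulated annually until extinction or age 100. Two arms
are compared: a reference arm in which obesity trends continue unabated,
and an intervention arm identical except that the eligible subset receives
surgery at baseline.

The causal chain is:

1. **Exposure.** BMI in each stratum follows a lognormal distribution,
   moment-matched to an arithmetic mean and SD and partitioned at the
   standard cutpoints 25/30/35/40 into five categories with proportions
   $p_i$. Each category is represented by its truncated-lognormal mean
   $m_i$, not the interval midpoint: the truncated mean preserves the
   distribution's mass and is the only well-defined choice for the open
   top category.
2. **Risk.** A per-BMI-unit relative risk $r$ for each disease expands to
   category relative risks $RR_i = r^{\,m_i - m_1}$ (category 1 is the
   reference). Surgery removes $\delta$ BMI units from the eligible
   categories, giving $RR_i' = \max(1,\; RR_i\, r^{-\delta})$ there, with
   category prevalences held constant. The proportional change in
   incidence is the potential impact fraction
   $$\mathrm{PIF} = \frac{\sum_i p_i RR_i - \sum_i p_i RR_i'}
                         {\sum_i p_i RR_i},$$
   applied as $I' = I\,(1 - \mathrm{PIF})$. The PIF is computed per
   stratum, per disease and per year, because the weight-loss trajectory
   and the secular BMI trend both move with time.
3. **Disease.** Each of the nine obesity-related diseases (five chronic
   conditions and four cancers) runs through a three-state illness-death
   life table -- well, diseased, dead-of-disease -- conditional on survival
   from all other causes. The recursion on conditional state fractions is
   $S_{x+1} = S_x(1-P_i) + C_x P_r$, $C_{x+1} = C_x(1-P_f-P_r) + S_x P_i$
   with $P_y = 1 - e^{-y_x}$. Prevalence $p_x = C_x/(S_x+C_x)$ yields the
   disease's mortality contribution $m_{dx} = f_x p_x$ and its
   disability-adjusted prevalence $p_x w_d$.
4. **Life table.** All-cause mortality $m^+$ and total disability
   ($\mathrm{pYLD}$ rate) $w^+$ are decomposed into "all other causes"
   residuals by subtracting the baseline disease terms, and recomposed with
   the post-intervention terms. The master table then computes
   $q_x = 1-e^{-m_x}$, survivors $l_x$, half-cycle life years
   $L_x = (l_x + l_{x+1})/2$, disability-adjusted life years
   $Lw_x = L_x(1-w_x)$, and life expectancies as tail sums. DALYs averted
   are the discounted differences in $Lw$ between arms.
5. **Economics.** The initial surgery cost is booked once per recipient at
   baseline; annual maintenance and complication costs apply to surviving
   recipients from post-operative year 3. Cost offsets price prevalent
   case-years averted (chronic diseases) and incident cases averted
   (cancers). Net cost = intervention + maintenance + offsets
   (+ unrelated-disease costs in one costing scenario), and the ICER is
   net cost per DALY averted, labelled *dominant* when the intervention
   both saves money and improves health.
6. **Uncertainty.** 3000 Monte Carlo iterations redraw the uncertain
   parameters jointly and rerun the whole chain, yielding 95% uncertainty
   intervals, cost-effectiveness probabilities and the CE plane.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Weight loss at year 2 / peak (year 3) | 27.4 / 32.0 | kg | Meta-analytic anchors of the piecewise-linear trajectory; stable after year 3 |
| kg per BMI unit | 3.2 | kg | 30 kg is quoted as roughly 10 BMI units in this population; configurable |
| Surgical mortality, years 1 and 2 | 0.0006, 0 | probability | Post-operative risk; zero from year 3 |
| Long-term complication risks | 0.01, 0.001, 0.002, 0.004 | /person-year | Gastric prolapse, band erosion, port infection, band removal; from year 3 |
| Surgery / maintenance / complications cost | 11 290 / 330 / 90 | 2003 AU$ | Baseline cost set; time-and-travel variant 12 452 / 1 126 / 105 |
| Discount rate | 0.03 | /year | Baseline; 0 and 0.06 in sensitivity analysis |
| BMI trend | 0.05 | BMI/year | Applied to the mean for at most 20 years, both arms |
| Weight-loss attenuation | 0.007 | fraction/year | Used only when the attenuation scenario is on; decays the peak over years 3-15 |

The attenuation default deserves a note: no follow-up series is bundled
with the package, so 0.7%/year is a configuration default with no claim
of fidelity -- the scenario exercises the code path, not a published
estimate.

## The synthetic world

No burden-of-disease, survey or costing microdata ship with the package.
`synth_config()` / `generate_inputs()` build a structurally realistic
stand-in:

* Gompertz all-cause mortality $a e^{bx}$ with sex-specific level, capped
  below 1; all-cause pYLD rising linearly with age, below 0.3.
* Nine diseases (four flagged as cancers; breast and endometrial cancer
  female-only) with exponentially age-increasing incidence and case
  fatality, zero remission for chronic conditions by default.
* Lognormal BMI with stratum means drawn from [24, 30] and SDs from
  [3, 6]; per-unit relative risks from [1.0, 1.4], constant across strata.
* Offset unit costs: AU$1 500-5 000 per prevalent case-year (chronic),
  AU$15 000-40 000 per incident case (cancers); unrelated-disease costs
  rising with age.

A consistency pass runs every disease's life table and rescales incidence
until total disease-attributable mortality and disability stay below 90%
of the all-cause rates at every age -- the proportional subtraction
requires positive residuals. Everything is deterministic given the seed;
write-then-read round trips are exact (values serialised at 17 significant
digits).

What a green test on this world establishes: the *mechanics* -- oracle
agreement, accounting identities, orderings across scenarios, Monte Carlo
determinism. What it does not establish: agreement with any published
Australian estimate. Published headline estimates for Australia rest on
national datasets that are not redistributable, and no target in this
package asserts them. Features of real data the generator does not
emulate: cohort effects in mortality, non-lognormal BMI tails, correlated
disease risks (e.g. diabetes raising cardiovascular incidence), and
age-dependent relative risks.

## Numerical choices

* **Rates to probabilities** via $P = 1 - e^{-m}$, with half-cycle life
  years: the standard actuarial conventions, declared explicitly since
  several discretisations are in circulation.
* **Discounting** is annual-discrete and end-of-year: a cohort's $t$-th
  year is weighted $(1+\rho)^{-t}$. The initial surgery cost is booked
  undiscounted at baseline; splitting it across its two bundled follow-up
  years would change results by less than reporting precision at 3%.
* **Initial prevalence** at age 20 comes from a 20-year burn-in at
  first-age rates (observed baseline prevalence is unavailable); an
  explicit `p_init` is accepted.
* **RR floor at 1** after shifting: a treated person cannot drop below
  reference risk -- the conservative choice.
* **Surgical mortality** combines with background mortality
  multiplicatively as an independent risk, scaled by the operated fraction
  at the population level.
* **Beta distributions** use the effective-count parameterisation
  $\alpha = pN$, $\beta = (1-p)N$; **gammas** are moment-matched; the
  zero-mean gamma (second-year surgical mortality, 0.0000 with SE 0.0002)
  cannot be a proper gamma and degenerates to a half-normal with scale SE,
  logged per run. Outpatient-frequency gammas with SE > mean (shape < 1)
  are accepted as printed and flagged in logs.
* **ICER uncertainty intervals** are rank-based on the CE plane:
  cost-saving iterations sort below all positive-ICER iterations, and
  percentile positions falling in the cost-saving block are reported as
  "dominant". The mean ICER is the ratio of mean net cost to mean DALYs
  averted (or "dominant" if mean net cost is negative).
* **Initial-cost uncertainty** is propagated by letting the sampled
  short-term resource items (outpatient frequencies, <2-year complication
  risks) scale a 30% variable share of the initial surgery cost. The
  70/30 split is an allocation assumption: the fixed share stands for
  theatre and device costs that those items do not price.

## Design decisions on open questions

* The intervention acts on disease **incidence only** (via the PIF);
  prevalent cases at baseline are not remitted by weight loss.
* The secular BMI trend shifts the **mean only**; the SD is held fixed.
* Whether pYLD differs by sex at equal age is configurable
  (`sex_specific_pyld`); the default generates sex-specific rates.
* Band removal does **not** revert weight loss by default
  (`band_removal_reverts = FALSE`); complications affect costs only. The
  flag exists because the question is genuinely open -- with reversal on,
  DALYs averted drop as bands are removed.
* Diabetes-to-cardiovascular risk linkage is excluded: the modelled
  diseases are independent given BMI.

## Known limitations

* **Categorical vs continuous PIF.** The five-category PIF is an
  approximation to a continuous-exposure PIF. For per-unit relative risks
  up to about 1.15 the two agree within 0.02 absolute (tested); beyond
  that the exponential risk function makes the continuous integral
  tail-dominated and the categorical version understates the impact
  fraction -- deviations reach 0.25 at $r = 1.4$ with a wide BMI
  distribution. Note the continuous integral over the full lognormal
  support actually diverges for $r > 1$ (exponential growth beats
  lognormal tail decay), so the comparison oracle truncates at a
  physiological ceiling of BMI 100; the divergence between the two methods
  is not an artefact of that cap. One acceptance test asserts the 0.02
  bound over the full generator range and is deliberately left failing
  with this analysis rather than weakening the bound.
* Closed cohorts: no migration or new entrants; results describe the 2003
  adult population, not a steady-state programme.
* Parameters without published uncertainty (disability weights, offset
  unit costs, maintenance costs) are held fixed in the PSA, so the
  reported intervals understate total uncertainty.
* Currency is 2003 AU$ by construction; no deflator table is implemented.

## Reproducing the analysis

```{r example, eval = FALSE}
inputs <- generate_inputs(synth_config(seed = 1))
ctx <- model_context(inputs)
evaluate_model(ctx, run_config("bmi40"))          # point estimates
run_scenario_grid(ctx, "bmi40")                   # sensitivity grid
run_monte_carlo(ctx, run_config("bmi40"))         # 3000-iteration PSA
```

The package-level acceptance report
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
recomputes the budget-impact quantities from their published inputs, from
scratch.
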