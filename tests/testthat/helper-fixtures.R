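# Shared fixtures, built once per test run. The default synthetic input set
# and its model context are moderately expensive (~0.5 s), so they are
# cached in a local environment and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

default_inputs <- function(seed = 1) {
  key <- paste0("inputs_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_inputs(synth_config(seed = seed))
  .fixture_cache[[key]]
}

default_ctx <- function(seed = 1) {
  key <- paste0("ctx_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- model_context(default_inputs(seed))
  .fixture_cache[[key]]
}

# A small single-disease epidemiology with constant rates, for oracle
# comparisons.
constant_epi <- function(i = 0.01, f = 0.02, r = 0, w = 0.3,
                         ages = 20:100) {
  disease_epidemiology("toy", i, f, r, disability_weight = w, ages = ages)
}

# Degenerate uncertainty set: every distribution collapses to its point
# estimate, so Monte Carlo must reproduce the deterministic run exactly.
degenerate_parameters <- function(ctx, spec = intervention_spec()) {
  pars <- list(
    uncertain_parameter("weight_loss_kg", "normal",
                        mean = spec$peak_loss_kg, se = 0,
                        role = "weight_loss"),
    uncertain_parameter("mortality_first_year", "gamma_mean_se",
                        mean = spec$mortality_first_year, se = 0,
                        role = "mortality_y1"),
    uncertain_parameter("mortality_second_year", "gamma_mean_se",
                        mean = spec$mortality_second_year, se = 0,
                        role = "mortality_y2"))
  rr <- ctx$rr_point
  for (j in seq_len(nrow(rr))) {
    pars[[length(pars) + 1L]] <- uncertain_parameter(
      paste0("rr_", rr$disease[j]), "relative_risk",
      rr = rr$rr_unit[j], ci = c(rr$rr_unit[j], rr$rr_unit[j]), role = "rr")
  }
  pars
}
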