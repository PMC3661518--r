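#' Run configuration for the full pipeline
#'
#' @param scenario Intervention scenario, `"bmi40"` or `"bmi35"`.
#' @param discount_rate Annual discount rate for costs and benefits,
#'   default 0.03 (sensitivity analyses use 0 and 0.06).
#' @param cost_variant `"baseline"` or `"time_travel"` (adds patients' time
#'   and travel costs).
#' @param include_offsets Include disease cost offsets in net cost
#'   (default `TRUE`; the exclusion scenario sets `FALSE`).
#' @param include_unrelated Add unrelated-disease costs in added life years
#'   (default `FALSE`; one costing scenario sets `TRUE`).
#' @param complication_multiplier Scaling of annual complication costs
#'   (10 for the higher-complications sensitivity analysis).
#' @param attenuation Use the 15-year weight-loss attenuation trajectory?
#' @param band_removal_reverts Should band removal gradually undo weight
#'   loss? Default `FALSE` (complications affect costs only).
#' @param seed Seed for input synthesis and Monte Carlo.
#' @param n_iterations Monte Carlo iterations, default 3000.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = c("bmi40", "bmi35"),
                       discount_rate = 0.03,
                       cost_variant = c("baseline", "time_travel"),
                       include_offsets = TRUE,
                       include_unrelated = FALSE,
                       complication_multiplier = 1,
                       attenuation = FALSE,
                       band_removal_reverts = FALSE,
                       seed = 1L,
                       n_iterations = 3000L) {
  scenario <- match.arg(scenario)
  cost_variant <- match.arg(cost_variant)
  stopifnot(discount_rate >= 0, discount_rate <= 1,
            complication_multiplier >= 0, n_iterations >= 1)
  structure(
    list(scenario = scenario, discount_rate = discount_rate,
         cost_variant = cost_variant, include_offsets = include_offsets,
         include_unrelated = include_unrelated,
         complication_multiplier = complication_multiplier,
         attenuation = isTRUE(attenuation),
         band_removal_reverts = isTRUE(band_removal_reverts),
         seed = as.integer(seed), n_iterations = as.integer(n_iterations)),
    class = "run_config"
  )
}

#' Short content hash of a configuration
#'
#' FNV-1a hash over the deparsed object; every emitted result row carries it
#' so output files can be traced back to the configuration that produced
#' them.
#'
#' @param config Any R object (typically a [run_config()]).
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Survivors matrix for all strata simultaneously: q is (ages x strata)
# annual death probabilities, cohorts enter at start_idx with init sizes.
# Returns an (ages+1 x strata) matrix of survivors at the start of each year
# (zero before cohort entry, zero at the closing row).
.survival_matrix <- function(q, start_idx, init) {
  nx <- nrow(q); ns <- ncol(q)
  l <- matrix(0, nx + 1L, ns)
  enter <- which(start_idx == 1L)
  l[1L, enter] <- init[enter]
  for (j in seq_len(nx)) {
    l[j + 1L, ] <- l[j, ] * (1 - q[j, ])
    enter <- which(start_idx == j + 1L)
    if (length(enter)) l[j + 1L, enter] <- init[enter]
  }
  l[nx + 1L, ] <- 0
  l
}

#' Precompute the model context for repeated evaluation
#'
#' Assembles everything that does not change between pipeline evaluations:
#' expanded rate arrays, BMI category proportions and truncated means per
#' stratum and year (with the secular trend applied), baseline disease
#' trajectories, the all-other-cause residual rates, and the reference-arm
#' master life tables. [evaluate_model()] then only recomputes what depends
#' on the intervention parameters, which keeps Monte Carlo runs cheap.
#'
#' @param inputs A `synthetic_inputs` object (see [generate_inputs()]).
#' @param spec An [intervention_spec()]; only the kg-to-BMI conversion is
#'   taken from it here.
#' @return An opaque list of class `model_context`.
#' @export
model_context <- function(inputs, spec = intervention_spec()) {
  stopifnot(inherits(inputs, "synthetic_inputs"))
  pop <- inputs$population
  ages <- pop$ages
  nx <- length(ages)
  strata <- pop$strata
  ns <- nrow(strata)
  strata$sex_idx <- match(strata$sex, colnames(pop$mortality))
  strata$start_idx <- match(strata$age_group, ages)

  diseases <- inputs$diseases
  nd <- length(diseases)
  ids <- vapply(diseases, `[[`, "", "id")
  cancer <- vapply(diseases, `[[`, TRUE, "cancer")
  w_d <- vapply(diseases, `[[`, 1.0, "disability_weight")
  unit_cost <- vapply(diseases, `[[`, 1.0, "unit_cost")

  inc <- array(0, c(nx, 2, nd)); cf <- inc; rem <- inc
  for (d in seq_len(nd)) for (s in 1:2) {
    inc[, s, d] <- diseases[[d]]$rates[[s]]$incidence
    cf[, s, d] <- diseases[[d]]$rates[[s]]$case_fatality
    rem[, s, d] <- diseases[[d]]$rates[[s]]$remission
  }

  # BMI category proportions / truncated means per stratum-year; the
  # secular trend shifts the mean for at most 20 years after baseline.
  bs <- inputs$bmi$strata_bmi
  key_in <- paste(strata$sex, strata$age_group)
  key_bmi <- paste(bs$sex, bs$age_group)
  bmi_row <- match(key_in, key_bmi)
  if (any(is.na(bmi_row)))
    stop("BMI inputs missing strata: ",
         paste(key_in[is.na(bmi_row)], collapse = ", "), call. = FALSE)
  P_arr <- array(0, c(5, ns, nx))
  M_arr <- array(0, c(5, ns, nx))
  for (s in seq_len(ns)) {
    b <- bs[bmi_row[s], ]
    shifts <- b$trend * pmin(pmax(ages - strata$age_group[s], 0), 20)
    for (sh in unique(shifts)) {
      ex <- bmi_exposure(b$bmi_mean + sh, b$bmi_sd)
      cols <- which(shifts == sh)
      P_arr[, s, cols] <- ex$p
      M_arr[, s, cols] <- ex$category_mean
    }
  }
  Ediff <- M_arr - rep(M_arr[1, , ], each = 5)

  elig <- list(
    bmi40 = vapply(seq_len(ns), function(s)
      sum(P_arr[5, s, strata$start_idx[s]]), 1.0),
    bmi35 = vapply(seq_len(ns), function(s)
      sum(P_arr[4:5, s, strata$start_idx[s]]), 1.0))

  # Baseline disease trajectories per (sex, disease); burn-in from age 0 at
  # first-age rates seeds the starting prevalence.
  K <- ns * nd
  sexmap <- rep(strata$sex_idx, times = nd)
  dmap <- rep(seq_len(nd), each = ns)
  p_ref <- array(0, c(nx, 2, nd))
  sfrac_ref <- array(0, c(nx, 2, nd))
  S0 <- matrix(0, 2, nd); C0 <- matrix(0, 2, nd)
  for (d in seq_len(nd)) for (s in 1:2) {
    init <- .burnin_init(inc[1, s, d], cf[1, s, d], rem[1, s, d],
                         years = ages[1])
    S0[s, d] <- init$S; C0[s, d] <- init$C
    st <- .disease_recursion(cbind(1 - exp(-inc[, s, d])),
                             cbind(1 - exp(-cf[, s, d])),
                             cbind(1 - exp(-rem[, s, d])),
                             init$S, init$C)
    alive <- st$S[, 1] + st$C[, 1]
    p_ref[, s, d] <- ifelse(alive > 0, st$C[, 1] / alive, 0)
    sfrac_ref[, s, d] <- ifelse(alive > 0, st$S[, 1] / alive, 1)
  }

  m_d_ref <- sapply(1:2, function(s)
    rowSums(matrix(cf[, s, ], nx, nd) * matrix(p_ref[, s, ], nx, nd)))
  w_d_ref <- sapply(1:2, function(s)
    as.numeric(matrix(p_ref[, s, ], nx, nd) %*% w_d))
  dec <- decompose_other_causes(
    c(pop$mortality), c(pop$pyld),
    cbind(c(m_d_ref)), cbind(c(w_d_ref)),
    ages = rep(ages, 2))
  m_other <- matrix(dec$m_other, nx, 2)
  w_other <- matrix(dec$w_other, nx, 2)

  # Per-(stratum, disease) expanded matrices for the vectorised recursion.
  inc_pair <- matrix(0, nx, K); Pf_pair <- inc_pair; Pr_pair <- inc_pair
  cf_pair <- inc_pair
  for (k in seq_len(K)) {
    s <- sexmap[k]; d <- dmap[k]
    inc_pair[, k] <- inc[, s, d]
    cf_pair[, k] <- cf[, s, d]
    Pf_pair[, k] <- 1 - exp(-cf[, s, d])
    Pr_pair[, k] <- 1 - exp(-rem[, s, d])
  }
  S0_pair <- S0[cbind(sexmap, dmap)]
  C0_pair <- C0[cbind(sexmap, dmap)]

  # Reference master life tables (whole stratum populations).
  m_plus_ref <- pop$mortality[, strata$sex_idx]
  w_plus_ref <- pop$pyld[, strata$sex_idx]
  q_ref <- 1 - exp(-m_plus_ref)
  l_ref <- .survival_matrix(q_ref, strata$start_idx, strata$population)
  L_ref <- (l_ref[seq_len(nx), ] + l_ref[-1L, ]) / 2
  Lw_ref <- L_ref * (1 - w_plus_ref)

  # Reference-arm disease quantities for cost offsets.
  p_ref_pair <- matrix(0, nx, K)
  cases_ref <- matrix(0, nx, K)
  for (k in seq_len(K)) {
    s <- sexmap[k]; d <- dmap[k]; st_col <- (k - 1L) %% ns + 1L
    p_ref_pair[, k] <- p_ref[, s, d]
    cases_ref[, k] <- sfrac_ref[, s, d] * (1 - exp(-inc[, s, d])) *
      l_ref[seq_len(nx), st_col]
  }
  PY_ref <- p_ref_pair * L_ref[, rep(seq_len(ns), nd)]

  # Years since cohort entry (used for discounting and the weight-loss
  # clock); negative before entry, masked to NA.
  tmat <- outer(seq_len(nx), strata$start_idx, `-`)
  tmat[tmat < 0] <- NA_integer_

  structure(
    list(ages = ages, nx = nx, strata = strata, ns = ns,
         mortality = pop$mortality, pyld = pop$pyld,
         unrelated_cost = pop$unrelated_cost,
         nd = nd, ids = ids, cancer = cancer, w_d = w_d,
         unit_cost = unit_cost, inc = inc, cf = cf, rem = rem,
         P_arr = P_arr, M_arr = M_arr, Ediff = Ediff, elig = elig,
         sexmap = sexmap, dmap = dmap,
         inc_pair = inc_pair, cf_pair = cf_pair, Pf_pair = Pf_pair,
         Pr_pair = Pr_pair, S0_pair = S0_pair, C0_pair = C0_pair,
         m_other = m_other, w_other = w_other,
         l_ref = l_ref, L_ref = L_ref, Lw_ref = Lw_ref,
         w_plus_ref = w_plus_ref,
         p_ref = p_ref, PY_ref = PY_ref, cases_ref = cases_ref,
         tmat = tmat, rr_point = inputs$bmi$rr,
         kg_per_bmi = spec$kg_per_bmi_unit),
    class = "model_context"
  )
}

#' Point-estimate parameter set
#'
#' The sampled quantities of the model at their point estimates: weight-loss
#' trajectory anchors, post-surgical mortality, per-disease relative risks
#' per BMI unit, and cost scalings (1 at baseline).
#'
#' @param ctx A [model_context()].
#' @param spec An [intervention_spec()].
#' @return A named list understood by [evaluate_model()].
#' @export
point_estimate_params <- function(ctx, spec = intervention_spec()) {
  list(peak_loss_kg = spec$peak_loss_kg,
       two_year_loss_kg = spec$two_year_loss_kg,
       mortality_first_year = spec$mortality_first_year,
       mortality_second_year = spec$mortality_second_year,
       rr_unit = ctx$rr_point$rr_unit,
       complication_cost_scale = 1,
       surgery_cost_scale = 1)
}

#' Evaluate the full model once
#'
#' Runs the whole chain -- weight-loss trajectory, potential impact
#' fractions, post-intervention disease life tables, master life tables,
#' DALYs averted, costs, net cost and ICER -- for one parameter set under
#' one configuration, against a prebuilt [model_context()].
#'
#' @param ctx A [model_context()].
#' @param config A [run_config()].
#' @param spec An [intervention_spec()] (trajectory shape and complication
#'   risks).
#' @param params Parameter list, default [point_estimate_params()].
#' @return An object of class `ce_outcome` with DALYs averted, cost
#'   components (AU$), net cost and the [icer()].
#' @export
evaluate_model <- function(ctx, config, spec = intervention_spec(),
                           params = point_estimate_params(ctx, spec)) {
  stopifnot(inherits(ctx, "model_context"), inherits(config, "run_config"))
  nx <- ctx$nx; ns <- ctx$ns; nd <- ctx$nd
  rate <- config$discount_rate
  ecat <- eligible_categories(config$scenario)
  elig <- ctx$elig[[config$scenario]]

  # Weight-loss clock: BMI units lost at each year since surgery.
  sp <- spec
  sp$peak_loss_kg <- params$peak_loss_kg
  sp$two_year_loss_kg <- min(params$two_year_loss_kg, params$peak_loss_kg)
  tvec <- 0:(nx - 1L)
  wl <- if (config$attenuation) attenuated_weight_loss_at(tvec, sp)
        else weight_loss_at(tvec, sp)
  if (config$band_removal_reverts) {
    keep <- (1 - spec$complication_risks[["band_removal"]])^pmax(0, tvec - 2)
    wl <- wl * keep
  }
  delta_vec <- wl / ctx$kg_per_bmi

  # Per-stratum, per-age BMI reduction (0 before cohort entry).
  tm <- ctx$tmat
  D <- matrix(0, nx, ns)
  has <- !is.na(tm)
  D[has] <- delta_vec[tm[has] + 1L]

  # Potential impact fractions per age, stratum, disease.
  PIF <- array(0, c(nx, ns, nd))
  shift_base <- t(D)                       # ns x nx
  for (d in seq_len(nd)) {
    rr <- params$rr_unit[d]
    if (rr <= 1) next
    RR <- rr^ctx$Ediff                     # 5 x ns x nx
    RRs <- RR
    fac <- rr^(-shift_base)
    for (i in ecat)
      RRs[i, , ] <- pmax(1, RR[i, , ] * fac)
    num <- colSums(ctx$P_arr * RR)         # ns x nx
    nums <- colSums(ctx$P_arr * RRs)
    PIF[, , d] <- t((num - nums) / num)
  }

  # Post-intervention disease life tables (all strata and diseases at once).
  PIF_pair <- matrix(PIF, nx, ns * nd)
  Pi_int <- 1 - exp(-ctx$inc_pair * (1 - PIF_pair))
  st <- .disease_recursion(Pi_int, ctx$Pf_pair, ctx$Pr_pair,
                           ctx$S0_pair, ctx$C0_pair)
  alive <- st$S + st$C
  p_int <- ifelse(alive > 0, st$C / alive, 0)
  sfrac_int <- ifelse(alive > 0, st$S / alive, 1)

  m_d_int <- ctx$cf_pair * p_int
  m_plus_int <- ctx$m_other[, ctx$strata$sex_idx] +
    rowSums(array(m_d_int, c(nx, ns, nd)), dims = 2)
  w_plus_int <- ctx$w_other[, ctx$strata$sex_idx] +
    rowSums(array(p_int, c(nx, ns, nd)) *
              rep(ctx$w_d, each = nx * ns), dims = 2)

  # Master life table, intervention arm. Surgical mortality acts on the
  # operated fraction of the stratum in post-operative years 1 and 2 only.
  q_surg <- matrix(0, nx, ns)
  q_surg[which(tm == 0)] <- params$mortality_first_year
  q_surg[which(tm == 1)] <- params$mortality_second_year
  q_int_base <- 1 - exp(-m_plus_int)
  q_int_pop <- 1 - (1 - q_int_base) *
    (1 - q_surg * rep(elig, each = nx))
  l_int <- .survival_matrix(q_int_pop, ctx$strata$start_idx,
                            ctx$strata$population)
  L_int <- (l_int[seq_len(nx), ] + l_int[-1L, ]) / 2
  Lw_int <- L_int * (1 - w_plus_int)

  disc <- matrix(0, nx, ns)
  disc[has] <- (1 + rate)^(-(tm[has] + 1))   # end-of-year discounting

  dalys <- sum((Lw_int - ctx$Lw_ref) * disc)
  dalys_undisc <- sum(Lw_int) - sum(ctx$Lw_ref)

  # Operated subset (for intervention and maintenance costs): full surgical
  # risk on top of the intervention-arm background mortality.
  n_operated <- ctx$strata$population * elig
  q_op <- 1 - (1 - q_int_base) * (1 - q_surg)
  l_op <- .survival_matrix(q_op, ctx$strata$start_idx, n_operated)
  L_op <- (l_op[seq_len(nx), ] + l_op[-1L, ]) / 2

  costs <- cost_set(config$cost_variant)
  annual <- costs$maintenance + costs$complications *
    params$complication_cost_scale * config$complication_multiplier
  maint_mask <- matrix(0, nx, ns)
  maint_mask[which(tm >= 2)] <- 1
  cost_initial <- sum(n_operated) * costs$surgery * params$surgery_cost_scale
  cost_maint <- annual * sum(L_op * disc * maint_mask)

  # Disease cost offsets: prevalent case-years averted for chronic
  # diseases, incident cases averted for cancers, discounted.
  L_rep <- L_int[, rep(seq_len(ns), nd)]
  PY_int <- p_int * L_rep
  cases_int <- sfrac_int * Pi_int *
    l_int[seq_len(nx), rep(seq_len(ns), nd)]
  disc_rep <- disc[, rep(seq_len(ns), nd)]
  unit_rep <- rep(ctx$unit_cost, each = ns)
  use_cases <- rep(ctx$cancer, each = ns)
  averted <- ctx$PY_ref - PY_int
  averted[, use_cases] <- ctx$cases_ref[, use_cases] - cases_int[, use_cases]
  cost_offsets_total <- -sum(colSums(averted * disc_rep) * unit_rep)

  cost_unrelated <- sum((L_int - ctx$L_ref) *
                          ctx$unrelated_cost[, ctx$strata$sex_idx] * disc)

  net <- cost_initial + cost_maint +
    (if (config$include_offsets) cost_offsets_total else 0) +
    (if (config$include_unrelated) cost_unrelated else 0)

  structure(
    list(scenario = config$scenario, discount_rate = rate,
         dalys_averted = dalys, dalys_undiscounted = dalys_undisc,
         cost_intervention = cost_initial, cost_maintenance = cost_maint,
         cost_offsets = cost_offsets_total, cost_unrelated = cost_unrelated,
         net_cost = net, icer = icer(net, dalys),
         n_operated = sum(n_operated), config_hash = config_hash(config)),
    class = "ce_outcome"
  )
}

#' @export
print.ce_outcome <- function(x, ...) {
  m <- function(v) format(round(v / 1e6), big.mark = " ")
  cat("Cost-effectiveness outcome [", x$scenario, ", ",
      sprintf("%.0f%%", 100 * x$discount_rate), " discount, config ",
      x$config_hash, "]\n", sep = "")
  cat("  persons operated:        ", format(round(x$n_operated),
                                            big.mark = " "), "\n")
  cat("  DALYs averted:           ", format(round(x$dalys_averted),
                                            big.mark = " "), "\n")
  cat("  intervention cost:       $", m(x$cost_intervention), "m\n", sep = "")
  cat("  maintenance+complic.:    $", m(x$cost_maintenance), "m\n", sep = "")
  cat("  cost offsets:            $", m(x$cost_offsets), "m\n", sep = "")
  if (x$cost_unrelated != 0)
    cat("  unrelated-disease cost:  $", m(x$cost_unrelated), "m\n", sep = "")
  cat("  net cost:                $", m(x$net_cost), "m\n", sep = "")
  cat("  ICER:                    ", format(x$icer), "\n", sep = "")
  invisible(x)
}

#' Run the pipeline end to end
#'
#' Synthesises inputs from the configured seed (unless supplied), builds the
#' model context and evaluates at point estimates. Optionally writes the
#' input tables and a summary JSON to `out_dir`.
#'
#' @param config A [run_config()].
#' @param inputs Optional `synthetic_inputs`; generated from
#'   `synth_config(seed = config$seed)` when `NULL`.
#' @param spec Optional [intervention_spec()]; defaults to the scenario in
#'   `config`.
#' @param out_dir Optional output directory.
#' @return A `ce_outcome`.
#' @export
run_pipeline <- function(config = run_config(), inputs = NULL, spec = NULL,
                         out_dir = NULL) {
  if (is.null(inputs)) inputs <- generate_inputs(synth_config(config$seed))
  if (is.null(spec)) spec <- intervention_spec(scenario = config$scenario)
  ctx <- model_context(inputs, spec)
  out <- evaluate_model(ctx, config, spec)
  if (!is.null(out_dir)) {
    write_synthetic_inputs(inputs, out_dir)
    summ <- unclass(out)
    summ$icer <- format(out$icer)
    jsonlite::write_json(summ, file.path(out_dir, "outcome.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Scenario grid: baseline plus sensitivity and costing scenarios
#'
#' Evaluates the model at point estimates under the standard set of
#' univariate scenarios: baseline (3% discount), 0% and 6% discount rates,
#' time-and-travel costs, excluding cost offsets, including
#' unrelated-disease costs, ten-fold complication costs, and 15-year
#' weight-loss attenuation.
#'
#' @param ctx A [model_context()] (or `NULL` to build one from `inputs`).
#' @param scenario `"bmi40"` or `"bmi35"`.
#' @param inputs Optional `synthetic_inputs` when `ctx` is `NULL`.
#' @param seed Seed used when inputs must be synthesised.
#' @return A data.frame with one row per scenario: cost components, net
#'   cost, DALYs averted, ICER and the config hash.
#' @export
run_scenario_grid <- function(ctx = NULL, scenario = c("bmi40", "bmi35"),
                              inputs = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  spec <- intervention_spec(scenario = scenario)
  if (is.null(ctx)) {
    if (is.null(inputs)) inputs <- generate_inputs(synth_config(seed))
    ctx <- model_context(inputs, spec)
  }
  base <- run_config(scenario = scenario, seed = seed)
  rows <- list(
    baseline = base,
    discount_0 = run_config(scenario, discount_rate = 0, seed = seed),
    discount_6 = run_config(scenario, discount_rate = 0.06, seed = seed),
    time_travel = run_config(scenario, cost_variant = "time_travel",
                             seed = seed),
    no_offsets = run_config(scenario, include_offsets = FALSE, seed = seed),
    unrelated_costs = run_config(scenario, include_unrelated = TRUE,
                                 seed = seed),
    complications_x10 = run_config(scenario, complication_multiplier = 10,
                                   seed = seed),
    attenuation_15y = run_config(scenario, attenuation = TRUE, seed = seed))
  out <- lapply(names(rows), function(nm) {
    r <- evaluate_model(ctx, rows[[nm]], spec)
    data.frame(scenario = scenario, variant = nm,
               cost_intervention = r$cost_intervention,
               cost_maintenance = r$cost_maintenance,
               cost_offsets = r$cost_offsets,
               cost_unrelated = r$cost_unrelated,
               net_cost = r$net_cost,
               dalys_averted = r$dalys_averted,
               icer = format(r$icer),
               config = r$config_hash)
  })
  do.call(rbind, out)
}
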