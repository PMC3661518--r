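#' Configuration for the synthetic input generator
#'
#' The generator emulates the *structure* of national burden-of-disease
#' inputs -- age-sex strata, Gompertz-like all-cause mortality, lognormal
#' BMI with mean around 27 and SD around 5, per-unit relative risks between
#' 1.0 and 1.4 -- without attempting to match any real country's values.
#'
#' @param seed Integer random seed; identical seed and config give
#'   byte-identical outputs.
#' @param n_diseases Number of modelled obesity-related diseases (default
#'   9, of which `n_cancers` are costed per incident case).
#' @param n_cancers Number of cancer-type diseases, default 4.
#' @param bmi_mean_range,bmi_sd_range Ranges the per-stratum arithmetic BMI
#'   mean and SD are drawn from (defaults `[24, 30]` and `[3, 6]`).
#' @param rr_range Range for the per-BMI-unit relative risks, default
#'   `[1.0, 1.4]`.
#' @param base_incidence_scale Multiplier on all disease incidence rates
#'   (0 gives disease-free populations).
#' @param mortality_a_range,mortality_b_range Ranges for the Gompertz
#'   parameters of all-cause mortality `m(x) = a * exp(b * x)`.
#' @param bmi_trend Annual additive increment to the mean BMI (units
#'   BMI/year), applied for at most 20 calendar years; default 0.05.
#' @param remission_rate Annual remission rate for non-cancer diseases,
#'   default 0 (chronic).
#' @param sex_specific_pyld Should the all-cause pYLD rate differ by sex at
#'   equal age? Default `TRUE`.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_diseases = 9L, n_cancers = 4L,
                         bmi_mean_range = c(24, 30),
                         bmi_sd_range = c(3, 6),
                         rr_range = c(1.0, 1.4),
                         base_incidence_scale = 1,
                         mortality_a_range = c(4e-5, 9e-5),
                         mortality_b_range = c(0.078, 0.088),
                         bmi_trend = 0.05,
                         remission_rate = 0,
                         sex_specific_pyld = TRUE) {
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  if (n_diseases < 1) stop("`n_diseases` must be >= 1", call. = FALSE)
  if (n_cancers < 0 || n_cancers > n_diseases)
    stop("`n_cancers` must lie in [0, n_diseases]", call. = FALSE)
  stopifnot(base_incidence_scale >= 0, bmi_trend >= 0, remission_rate >= 0)
  structure(
    list(seed = as.integer(seed), n_diseases = as.integer(n_diseases),
         n_cancers = as.integer(n_cancers),
         bmi_mean_range = bmi_mean_range, bmi_sd_range = bmi_sd_range,
         rr_range = rr_range, base_incidence_scale = base_incidence_scale,
         mortality_a_range = mortality_a_range,
         mortality_b_range = mortality_b_range,
         bmi_trend = bmi_trend, remission_rate = remission_rate,
         sex_specific_pyld = sex_specific_pyld,
         ages = 20:100, age_groups = seq(20L, 95L, 5L),
         sexes = c("male", "female")),
    class = "synth_config"
  )
}

# One row per age-sex stratum, age-major with male first; shared by every
# generator so positional alignment across tables is guaranteed.
.strata_frame <- function(config) {
  out <- expand.grid(sex = config$sexes, age_group = config$age_groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.default_disease_names <- function(n, n_cancers) {
  chronic <- c("ischemic_heart_disease", "stroke",
               "hypertensive_heart_disease", "diabetes", "osteoarthritis")
  cancers <- c("breast_cancer", "colon_cancer", "endometrial_cancer",
               "kidney_cancer")
  n_chronic <- n - n_cancers
  ch <- if (n_chronic <= length(chronic)) chronic[seq_len(max(0, n_chronic))]
        else c(chronic, paste0("chronic_", seq_len(n_chronic - length(chronic))))
  ca <- if (n_cancers <= length(cancers)) cancers[seq_len(max(0, n_cancers))]
        else c(cancers, paste0("cancer_", seq_len(n_cancers - length(cancers))))
  c(ch, ca)
}

#' Generate age-sex population, mortality and disability inputs
#'
#' All-cause mortality follows a Gompertz curve `a * exp(b * age)` with
#' sex-specific parameters drawn from the configured ranges (female `a`
#' scaled down 20%), capped below 1. The all-cause pYLD (prevalent years
#' lived with disability) rate rises linearly with age and stays below 0.3.
#' An annual unrelated-disease treatment cost per life-year (used by one
#' costing scenario) rises with age alongside.
#'
#' @param config A [synth_config()].
#' @return Object of class `population_inputs`: list with `strata` (data
#'   frame sex / age_group / population), `mortality` and `pyld` (81 x 2
#'   matrices, ages 20-100 by sex) and `unrelated_cost` (same shape, AU$
#'   per life-year).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ages <- config$ages
  nx <- length(ages)

  a <- stats::runif(1, config$mortality_a_range[1], config$mortality_a_range[2])
  b <- stats::runif(1, config$mortality_b_range[1], config$mortality_b_range[2])
  a_sex <- c(male = a, female = 0.8 * a)
  mortality <- sapply(a_sex, function(ai) pmin(ai * exp(b * ages), 0.999))

  w0 <- stats::runif(2, 0.02, 0.04)
  w1 <- stats::runif(2, 0.0020, 0.0028)
  if (!config$sex_specific_pyld) { w0[2] <- w0[1]; w1[2] <- w1[1] }
  pyld <- sapply(1:2, function(s) pmin(w0[s] + w1[s] * (ages - 20), 0.29))
  colnames(pyld) <- config$sexes

  strata <- .strata_frame(config)
  base <- 640000 * exp(-0.00045 * (strata$age_group - 20)^2)
  strata$population <- round(base * stats::runif(nrow(strata), 0.95, 1.05))

  unrelated <- sapply(1:2, function(s)
    (1500 + 55 * (ages - 20)) * stats::runif(1, 0.9, 1.1))
  colnames(unrelated) <- config$sexes

  structure(
    list(strata = strata, ages = ages, mortality = mortality, pyld = pyld,
         unrelated_cost = unrelated),
    class = "population_inputs"
  )
}

#' Generate the modelled disease set
#'
#' Draws per-disease, per-sex incidence and case-fatality curves (both
#' rising exponentially with age), a disability weight, and an offset unit
#' cost: per prevalent case-year for chronic diseases, per incident case for
#' cancers. Remission is zero for chronic diseases unless configured
#' otherwise. With the default nine diseases, breast and endometrial cancer
#' are female-only.
#'
#' The proportional life table requires total disease-attributable mortality
#' and disability to stay below the all-cause rates at every age; when
#' `population` is supplied (or generated internally) the implied disease
#' mortality/pYLD are checked by running each disease's life table, and all
#' incidence rates are scaled down (logged via `message()`) until the
#' margin holds.
#'
#' @param config A [synth_config()].
#' @param population Optional [generate_population()] output used for the
#'   consistency check; generated from the same config when `NULL`.
#' @return Object of class `disease_set`: a list of disease records, each
#'   with `id`, `cancer`, `disability_weight`, `unit_cost` and per-sex rate
#'   vectors under `rates$male` / `rates$female`.
#' @export
generate_disease_set <- function(config, population = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(population)) population <- generate_population(config)
  set.seed(config$seed + 1000L)
  ages <- config$ages
  nd <- config$n_diseases
  ids <- .default_disease_names(nd, config$n_cancers)
  cancer <- c(rep(FALSE, nd - config$n_cancers), rep(TRUE, config$n_cancers))
  female_only <- ids %in% c("breast_cancer", "endometrial_cancer")

  diseases <- vector("list", nd)
  for (d in seq_len(nd)) {
    i0 <- if (cancer[d]) stats::runif(1, 2e-5, 8e-5)
          else stats::runif(1, 8e-5, 3e-4)
    gi <- stats::runif(1, 0.035, 0.05)
    f0 <- if (cancer[d]) stats::runif(1, 0.01, 0.04)
          else stats::runif(1, 0.002, 0.008)
    gf <- stats::runif(1, 0.018, 0.028)
    dw <- stats::runif(1, 0.02, 0.12)
    uc <- if (cancer[d]) stats::runif(1, 15000, 40000)
          else stats::runif(1, 1500, 5000)
    sex_mult <- stats::runif(2, 0.7, 1.3)
    if (female_only[d]) sex_mult[1] <- 0
    rates <- lapply(1:2, function(s) {
      inc <- config$base_incidence_scale * sex_mult[s] * i0 *
        exp(gi * (ages - 20))
      list(incidence = inc,
           case_fatality = f0 * exp(gf * (ages - 20)),
           remission = rep(if (cancer[d]) 0 else config$remission_rate,
                           length(ages)))
    })
    names(rates) <- config$sexes
    diseases[[d]] <- list(id = ids[d], cancer = cancer[d],
                          disability_weight = dw, unit_cost = uc,
                          rates = rates)
  }
  out <- structure(diseases, class = "disease_set",
                   ages = ages, sexes = config$sexes)
  .enforce_consistency(out, population, config)
}

# Scale incidence down until summed disease mortality and pYLD stay under
# 90% of the all-cause rates at every age (needed so the proportional
# subtraction leaves positive all-other-cause rates).
.enforce_consistency <- function(diseases, population, config,
                                 margin = 0.9, max_iter = 25L) {
  for (iter in seq_len(max_iter)) {
    ok <- TRUE
    for (s in 1:2) {
      m_sum <- 0; w_sum <- 0
      for (d in diseases) {
        epi <- disease_epidemiology(
          d$id, d$rates[[s]]$incidence, d$rates[[s]]$case_fatality,
          d$rates[[s]]$remission, d$disability_weight, d$cancer,
          ages = attr(diseases, "ages"))
        traj <- run_disease_lifetable(epi)
        m_sum <- m_sum + traj$mortality
        w_sum <- w_sum + traj$pyld
      }
      if (any(m_sum > margin * population$mortality[, s]) ||
          any(w_sum > margin * population$pyld[, s])) ok <- FALSE
    }
    if (ok) return(diseases)
    message("synthetic disease burden exceeds all-cause rates; ",
            "scaling incidence by 0.7 (pass ", iter, ")")
    for (d in seq_along(diseases)) {
      for (s in 1:2) {
        diseases[[d]]$rates[[s]]$incidence <-
          0.7 * diseases[[d]]$rates[[s]]$incidence
      }
    }
  }
  stop("could not reconcile disease burden with all-cause rates",
       call. = FALSE)
}

#' Extract one disease-sex stratum as a `disease_epidemiology`
#'
#' @param diseases A `disease_set`.
#' @param id Disease id (or integer index).
#' @param sex `"male"` or `"female"`.
#' @return A [disease_epidemiology()] object.
#' @export
as_disease_epidemiology <- function(diseases, id, sex = c("male", "female")) {
  stopifnot(inherits(diseases, "disease_set"))
  sex <- match.arg(sex)
  idx <- if (is.numeric(id)) id
         else which(vapply(diseases, `[[`, "", "id") == id)
  if (length(idx) != 1L || idx < 1 || idx > length(diseases))
    stop("unknown disease: ", id, call. = FALSE)
  d <- diseases[[idx]]
  disease_epidemiology(d$id, d$rates[[sex]]$incidence,
                       d$rates[[sex]]$case_fatality, d$rates[[sex]]$remission,
                       d$disability_weight, d$cancer,
                       ages = attr(diseases, "ages"))
}

#' Generate BMI distribution and relative-risk inputs
#'
#' Per-stratum arithmetic BMI mean and SD (lognormal on the BMI scale), the
#' annual BMI-trend increment, and one relative risk per BMI unit per
#' disease (constant across strata) with a synthetic 95% CI for the
#' uncertainty analysis.
#'
#' @param config A [synth_config()].
#' @param diseases Optional `disease_set` supplying disease ids; generated
#'   from the config when `NULL`.
#' @return List of class `bmi_inputs` with `strata_bmi` (data frame: sex,
#'   age_group, bmi_mean, bmi_sd, trend) and `rr` (data frame: disease,
#'   rr_unit, rr_lo, rr_hi).
#' @export
generate_bmi_inputs <- function(config, diseases = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(diseases)) diseases <- generate_disease_set(config)
  set.seed(config$seed + 2000L)
  strata <- .strata_frame(config)
  n <- nrow(strata)
  strata$bmi_mean <- stats::runif(n, config$bmi_mean_range[1],
                                  config$bmi_mean_range[2])
  strata$bmi_sd <- stats::runif(n, config$bmi_sd_range[1],
                                config$bmi_sd_range[2])
  strata$trend <- rep(config$bmi_trend, n)

  ids <- vapply(diseases, `[[`, "", "id")
  rr_unit <- stats::runif(length(ids), config$rr_range[1], config$rr_range[2])
  log_se <- stats::runif(length(ids), 0.01, 0.05)
  rr <- data.frame(disease = ids, rr_unit = rr_unit,
                   rr_lo = rr_unit * exp(-1.96 * log_se),
                   rr_hi = rr_unit * exp(1.96 * log_se))
  structure(list(strata_bmi = strata, rr = rr), class = "bmi_inputs")
}

#' Generate a complete, internally consistent model input set
#'
#' Bundles [generate_population()], [generate_disease_set()] (validated
#' against the population) and [generate_bmi_inputs()] under one seed.
#'
#' @param config A [synth_config()].
#' @return Object of class `synthetic_inputs` with elements `config`,
#'   `population`, `diseases`, `bmi`.
#' @export
generate_inputs <- function(config = synth_config()) {
  population <- generate_population(config)
  diseases <- generate_disease_set(config, population)
  bmi <- generate_bmi_inputs(config, diseases)
  structure(list(config = config, population = population,
                 diseases = diseases, bmi = bmi),
            class = "synthetic_inputs")
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write synthetic inputs to plain-text files
#'
#' Writes `population.csv`, `diseases.csv`, `bmi.csv` and `rr.csv` (long
#' format) plus a `config.json` echo into `dir`. Numeric values are written
#' with 17 significant digits so a read-write round trip reproduces them
#' exactly.
#'
#' @param inputs A `synthetic_inputs` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(inputs, dir) {
  stopifnot(inherits(inputs, "synthetic_inputs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- inputs$population
  ages <- pop$ages

  rows <- list()
  for (s in 1:2) {
    sex <- colnames(pop$mortality)[s]
    rows[[length(rows) + 1L]] <- data.frame(
      sex = sex, age = ages, quantity = "mortality",
      value = .fmt_num(pop$mortality[, s]))
    rows[[length(rows) + 1L]] <- data.frame(
      sex = sex, age = ages, quantity = "pyld",
      value = .fmt_num(pop$pyld[, s]))
    rows[[length(rows) + 1L]] <- data.frame(
      sex = sex, age = ages, quantity = "unrelated_cost",
      value = .fmt_num(pop$unrelated_cost[, s]))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    sex = pop$strata$sex, age = pop$strata$age_group,
    quantity = "population", value = .fmt_num(pop$strata$population))
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "population.csv"), row.names = FALSE)

  drows <- list()
  for (d in inputs$diseases) {
    for (sex in names(d$rates)) {
      for (q in c("incidence", "case_fatality", "remission")) {
        drows[[length(drows) + 1L]] <- data.frame(
          disease = d$id, sex = sex, age = ages, quantity = q,
          value = .fmt_num(d$rates[[sex]][[q]]))
      }
    }
    drows[[length(drows) + 1L]] <- data.frame(
      disease = d$id, sex = NA, age = NA,
      quantity = c("disability_weight", "unit_cost", "cancer"),
      value = c(.fmt_num(d$disability_weight), .fmt_num(d$unit_cost),
                as.character(as.integer(d$cancer))))
  }
  utils::write.csv(do.call(rbind, drows),
                   file.path(dir, "diseases.csv"), row.names = FALSE)

  bs <- inputs$bmi$strata_bmi
  brows <- do.call(rbind, lapply(c("bmi_mean", "bmi_sd", "trend"),
    function(q) data.frame(sex = bs$sex, age_group = bs$age_group,
                           quantity = q, value = .fmt_num(bs[[q]]))))
  utils::write.csv(brows, file.path(dir, "bmi.csv"), row.names = FALSE)

  rr <- inputs$bmi$rr
  rrows <- do.call(rbind, lapply(c("rr_unit", "rr_lo", "rr_hi"),
    function(q) data.frame(disease = rr$disease, quantity = q,
                           value = .fmt_num(rr[[q]]))))
  utils::write.csv(rrows, file.path(dir, "rr.csv"), row.names = FALSE)

  cfg <- inputs$config
  cfg_plain <- unclass(cfg)
  jsonlite::write_json(cfg_plain, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read synthetic inputs back from disk
#'
#' Inverse of [write_synthetic_inputs()].
#'
#' @param dir Directory containing the CSV/JSON files.
#' @return A `synthetic_inputs` object.
#' @export
read_synthetic_inputs <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  config <- synth_config(
    seed = cfg_raw$seed, n_diseases = cfg_raw$n_diseases,
    n_cancers = cfg_raw$n_cancers, bmi_mean_range = cfg_raw$bmi_mean_range,
    bmi_sd_range = cfg_raw$bmi_sd_range, rr_range = cfg_raw$rr_range,
    base_incidence_scale = cfg_raw$base_incidence_scale,
    mortality_a_range = cfg_raw$mortality_a_range,
    mortality_b_range = cfg_raw$mortality_b_range,
    bmi_trend = cfg_raw$bmi_trend, remission_rate = cfg_raw$remission_rate,
    sex_specific_pyld = cfg_raw$sex_specific_pyld)
  ages <- config$ages

  pop_raw <- utils::read.csv(file.path(dir, "population.csv"))
  get_mat <- function(q) {
    m <- sapply(config$sexes, function(sx) {
      sub <- pop_raw[pop_raw$quantity == q & pop_raw$sex == sx, ]
      sub$value[order(sub$age)]
    })
    colnames(m) <- config$sexes
    m
  }
  counts <- pop_raw[pop_raw$quantity == "population", ]
  strata <- data.frame(sex = counts$sex, age_group = counts$age,
                       population = counts$value)
  population <- structure(
    list(strata = strata, ages = ages, mortality = get_mat("mortality"),
         pyld = get_mat("pyld"), unrelated_cost = get_mat("unrelated_cost")),
    class = "population_inputs")

  d_raw <- utils::read.csv(file.path(dir, "diseases.csv"))
  ids <- unique(d_raw$disease)
  diseases <- lapply(ids, function(id) {
    sub <- d_raw[d_raw$disease == id, ]
    scal <- function(q) as.numeric(sub$value[sub$quantity == q][1])
    rates <- lapply(config$sexes, function(sx) {
      g <- function(q) {
        r <- sub[sub$quantity == q & !is.na(sub$sex) & sub$sex == sx, ]
        as.numeric(r$value[order(r$age)])
      }
      list(incidence = g("incidence"), case_fatality = g("case_fatality"),
           remission = g("remission"))
    })
    names(rates) <- config$sexes
    list(id = id, cancer = scal("cancer") == 1,
         disability_weight = scal("disability_weight"),
         unit_cost = scal("unit_cost"), rates = rates)
  })
  diseases <- structure(diseases, class = "disease_set",
                        ages = ages, sexes = config$sexes)

  b_raw <- utils::read.csv(file.path(dir, "bmi.csv"))
  key <- b_raw[b_raw$quantity == "bmi_mean", c("sex", "age_group")]
  strata_bmi <- data.frame(
    sex = key$sex, age_group = key$age_group,
    bmi_mean = b_raw$value[b_raw$quantity == "bmi_mean"],
    bmi_sd = b_raw$value[b_raw$quantity == "bmi_sd"],
    trend = b_raw$value[b_raw$quantity == "trend"])
  rr_raw <- utils::read.csv(file.path(dir, "rr.csv"))
  rr <- data.frame(
    disease = rr_raw$disease[rr_raw$quantity == "rr_unit"],
    rr_unit = rr_raw$value[rr_raw$quantity == "rr_unit"],
    rr_lo = rr_raw$value[rr_raw$quantity == "rr_lo"],
    rr_hi = rr_raw$value[rr_raw$quantity == "rr_hi"])
  bmi <- structure(list(strata_bmi = strata_bmi, rr = rr),
                   class = "bmi_inputs")

  structure(list(config = config, population = population,
                 diseases = diseases, bmi = bmi),
            class = "synthetic_inputs")
}
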