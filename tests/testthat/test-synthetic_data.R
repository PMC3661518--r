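test_that("generation is deterministic under a fixed seed", {
  a <- generate_inputs(synth_config(seed = 7))
  b <- generate_inputs(synth_config(seed = 7))
  expect_identical(a, b)
  c <- generate_inputs(synth_config(seed = 8))
  expect_false(identical(a$population$mortality, c$population$mortality))
})

test_that("population inputs respect their invariants", {
  pop <- generate_population(synth_config(seed = 3))
  expect_equal(nrow(pop$strata), 32)
  expect_setequal(unique(pop$strata$age_group), seq(20, 95, 5))
  expect_true(all(pop$strata$population >= 0))
  expect_true(all(pop$mortality > 0 & pop$mortality <= 1))
  expect_true(all(pop$pyld >= 0 & pop$pyld < 0.3))
  # mortality non-decreasing above age 60
  over60 <- pop$ages >= 60
  expect_true(all(diff(pop$mortality[over60, 1]) >= 0))
  expect_true(all(diff(pop$mortality[over60, 2]) >= 0))
  # Gompertz gradient: age 90 vs age 40 in every sex
  expect_true(all(pop$mortality[match(90, pop$ages), ] >
                    pop$mortality[match(40, pop$ages), ]))
})

test_that("degenerate scales produce empty processes", {
  cfg0 <- synth_config(seed = 1, mortality_a_range = c(0, 0))
  pop0 <- generate_population(cfg0)
  expect_true(all(pop0$mortality == 0))

  cfg_i0 <- synth_config(seed = 1, base_incidence_scale = 0)
  dis0 <- generate_disease_set(cfg_i0)
  for (d in dis0) {
    expect_true(all(d$rates$male$incidence == 0))
    expect_true(all(d$rates$female$incidence == 0))
  }
})

test_that("disease set has the configured structure", {
  dis <- generate_disease_set(synth_config(seed = 2))
  expect_length(dis, 9)
  expect_equal(sum(vapply(dis, `[[`, TRUE, "cancer")), 4)
  ws <- vapply(dis, `[[`, 1.0, "disability_weight")
  expect_true(all(ws > 0 & ws < 1))
  expect_identical(generate_disease_set(synth_config(seed = 2)), dis)
  expect_error(as_disease_epidemiology(dis, "nonexistent", "male"),
               "unknown disease")
})

test_that("total disease burden stays below all-cause rates", {
  inputs <- default_inputs()
  for (s in 1:2) {
    m_sum <- 0; w_sum <- 0
    for (d in seq_along(inputs$diseases)) {
      epi <- as_disease_epidemiology(inputs$diseases, d,
                                     c("male", "female")[s])
      traj <- run_disease_lifetable(epi)
      m_sum <- m_sum + traj$mortality
      w_sum <- w_sum + traj$pyld
    }
    expect_true(all(m_sum < inputs$population$mortality[, s]))
    expect_true(all(w_sum < inputs$population$pyld[, s]))
  }
})

test_that("BMI inputs respect ranges and degenerate configs", {
  bmi <- generate_bmi_inputs(synth_config(seed = 4))
  expect_true(all(bmi$strata_bmi$bmi_mean >= 24 & bmi$strata_bmi$bmi_mean <= 30))
  expect_true(all(bmi$strata_bmi$bmi_sd >= 3 & bmi$strata_bmi$bmi_sd <= 6))
  expect_true(all(bmi$rr$rr_unit >= 1 & bmi$rr$rr_unit <= 1.4))
  expect_true(all(bmi$rr$rr_lo <= bmi$rr$rr_unit &
                    bmi$rr$rr_unit <= bmi$rr$rr_hi))
  expect_equal(bmi$strata_bmi$trend, rep(0.05, 32))

  flat <- generate_bmi_inputs(synth_config(seed = 4, rr_range = c(1, 1)))
  expect_equal(flat$rr$rr_unit, rep(1, 9))
})

test_that("config validation rejects bad settings", {
  expect_error(synth_config(seed = "x"), "integer")
  expect_error(synth_config(n_diseases = 0), ">= 1")
  expect_error(synth_config(n_diseases = 3, n_cancers = 5), "n_cancers")
})

test_that("write/read round trip reproduces every value exactly", {
  inputs <- default_inputs()
  dir <- withr::local_tempdir()
  write_synthetic_inputs(inputs, dir)
  back <- read_synthetic_inputs(dir)
  expect_equal(back$population$mortality, inputs$population$mortality,
               tolerance = 0)
  expect_equal(back$population$pyld, inputs$population$pyld, tolerance = 0)
  expect_equal(back$population$strata$population,
               inputs$population$strata$population, tolerance = 0)
  for (d in seq_along(inputs$diseases)) {
    expect_identical(back$diseases[[d]]$id, inputs$diseases[[d]]$id)
    expect_equal(back$diseases[[d]]$rates$male$incidence,
                 inputs$diseases[[d]]$rates$male$incidence, tolerance = 0)
    expect_equal(back$diseases[[d]]$disability_weight,
                 inputs$diseases[[d]]$disability_weight, tolerance = 0)
  }
  expect_equal(back$bmi$strata_bmi$bmi_mean, inputs$bmi$strata_bmi$bmi_mean,
               tolerance = 0)
  expect_equal(back$bmi$rr$rr_unit, inputs$bmi$rr$rr_unit, tolerance = 0)

  # byte-identical files on re-write
  dir2 <- withr::local_tempdir()
  write_synthetic_inputs(inputs, dir2)
  for (f in c("population.csv", "diseases.csv", "bmi.csv", "rr.csv")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})
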