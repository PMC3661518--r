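test_that("decompose subtracts disease terms and flags inconsistency", {
  m_all <- rep(0.05, 3)
  w_all <- rep(0.10, 3)
  m_d <- cbind(rep(0.01, 3), rep(0.005, 3))
  w_d <- cbind(rep(0.02, 3), rep(0.01, 3))
  dec <- decompose_other_causes(m_all, w_all, m_d, w_d)
  expect_equal(dec$m_other, rep(0.035, 3))
  expect_equal(dec$w_other, rep(0.07, 3))

  # no diseases: identity
  dec0 <- decompose_other_causes(m_all, w_all, matrix(0, 3, 1),
                                 matrix(0, 3, 1))
  expect_equal(dec0$m_other, m_all)
  expect_equal(dec0$w_other, w_all)

  # error names the offending age
  m_bad <- m_d; m_bad[2, 1] <- 0.2
  expect_error(
    decompose_other_causes(m_all, w_all, m_bad, w_d, ages = c(69, 70, 71)),
    "mortality exceeds.*age 70")
  w_bad <- w_d; w_bad[3, 2] <- 0.5
  expect_error(
    decompose_other_causes(m_all, w_all, m_d, w_bad, ages = c(69, 70, 71)),
    "pYLD exceeds.*age 71")
})

test_that("recompose is the exact inverse of decompose", {
  set.seed(21)
  for (k in 1:10) {
    nd <- sample(1:9, 1)
    m_d <- matrix(runif(81 * nd, 0, 0.002), 81, nd)
    w_d <- matrix(runif(81 * nd, 0, 0.005), 81, nd)
    m_all <- rowSums(m_d) + runif(81, 0.001, 0.1)
    w_all <- rowSums(w_d) + runif(81, 0.01, 0.2)
    dec <- decompose_other_causes(m_all, w_all, m_d, w_d)
    rec <- recompose_total(dec$m_other, dec$w_other, m_d, w_d)
    expect_equal(rec$m_total, m_all, tolerance = 1e-14)
    expect_equal(rec$w_total, w_all, tolerance = 1e-14)
  }
  # additivity example
  rec <- recompose_total(0.035, 0.05, cbind(0.008, 0.004), cbind(0, 0))
  expect_equal(rec$m_total, 0.047)
})

test_that("zero-mortality cohort has closed-form life expectancy", {
  lt <- run_master_lifetable(rep(0, 81), rep(0, 81), start_age = 20)
  expect_equal(lt$l, rep(1, 81))
  expect_equal(lt$e[1], 80.5)  # survives to the forced closure at 100
  expect_equal(lt$Lw, lt$L)
})

test_that("constant-mortality table equals the loop oracle", {
  m <- rep(0.02, 81)
  w <- seq(0.05, 0.25, length.out = 81)
  lt <- run_master_lifetable(m, w, start_age = 20, cohort_size = 1000)
  oracle <- oracle_lifetable_loop(m, w, 20, cohort = 1000)
  expect_equal(lt$l, oracle$l, tolerance = 1e-10)
  expect_equal(lt$L, oracle$L, tolerance = 1e-10)
  expect_equal(lt$Lw, oracle$Lw, tolerance = 1e-10)
  expect_true(all(diff(lt$l) <= 0))
  expect_true(all(lt$q >= 0 & lt$q <= 1))
})

test_that("extra mortality combines as an independent risk", {
  m <- rep(0.01, 6)
  extra <- c(0.0006, 0, 0, 0, 0, 0)
  lt <- run_master_lifetable(m, rep(0, 6), start_age = 95,
                             extra_mortality = extra)
  expect_equal(lt$q[1], 1 - exp(-0.01) * (1 - 0.0006), tolerance = 1e-15)
  oracle <- oracle_lifetable_loop(m, rep(0, 6), 95, extra = extra)
  expect_equal(lt$L, oracle$L, tolerance = 1e-12)
})

test_that("dalys_averted discounts annual Lw differences", {
  make_fake <- function(Lw, start_age) {
    out <- data.frame(age = start_age + seq_along(Lw) - 1L, Lw = Lw)
    attr(out, "start_age") <- start_age
    class(out) <- c("cohort_lifetable", class(out))
    out
  }
  ref <- make_fake(c(0, 0), 60)
  int <- make_fake(c(10, 10), 60)
  # 10/1.03 + 10/1.03^2, computed independently: 19.1346971...
  expect_equal(dalys_averted(ref, int, 0.03), 10 / 1.03 + 10 / 1.03^2)
  expect_equal(dalys_averted(ref, int, 0.03), 19.13470, tolerance = 1e-6)
  expect_equal(dalys_averted(ref, int, 0), 20)
  expect_equal(dalys_averted(ref, ref, 0.03), 0)
  expect_error(dalys_averted(list(ref, ref), list(int), 0.03), "strata")
})

test_that("null intervention leaves the master table unchanged", {
  ctx <- default_ctx()
  m_d <- sapply(1:9, function(d) ctx$cf[, 1, d] * ctx$p_ref[, 1, d])
  w_d <- sapply(1:9, function(d) ctx$p_ref[, 1, d] * ctx$w_d[d])
  rec <- recompose_total(ctx$m_other[, 1], ctx$w_other[, 1], m_d, w_d)
  expect_equal(rec$m_total, ctx$mortality[, 1], tolerance = 1e-12)
  expect_equal(rec$w_total, ctx$pyld[, 1], tolerance = 1e-12)
})
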