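test_that("generation is reproducible and respects its invariants", {
  lt <- test_lifetable()
  spec <- cohort_spec(n = 2000)
  a <- generate_cohort(spec, lt, seed = 5)
  b <- generate_cohort(spec, lt, seed = 5)
  c <- generate_cohort(spec, lt, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
  # truth always known; follow-up positive; ages integer in range
  expect_false(anyNA(a$stage_true))
  expect_true(all(a$time > 0))
  expect_true(all(a$age_at_dx >= 18 & a$age_at_dx <= 99))
  # administrative censoring: nobody followed past the censoring horizon,
  # and survivors at the horizon are censored, not events
  horizon <- as.numeric(spec$censor_date + 1 - a$dx_date) / 365.25
  expect_true(all(a$time <= horizon + 1e-12))
  at_horizon <- abs(a$time - horizon) < 1e-12
  expect_true(all(a$event[at_horizon] == 0))
})

test_that("realised stage mix matches the registry default within 1 pp", {
  lt <- test_lifetable()
  co <- generate_cohort(cohort_spec(n = 50000), lt, seed = 7)
  mix <- prop.table(table(co$stage_true))
  expect_equal(unname(mix[["localised"]]), 0.400, tolerance = 0.01)
  expect_equal(unname(mix[["regional"]]), 0.365, tolerance = 0.01)
  expect_equal(unname(mix[["distant"]]), 0.235, tolerance = 0.01)
})

test_that("baseline missingness is small and age-dependent", {
  co <- test_cohort()
  p_miss <- mean(co$stage_obs == "missing")
  expect_gt(p_miss, 0.01)
  expect_lt(p_miss, 0.08)
  expect_gt(mean(co$age_at_dx[co$stage_obs == "missing"]),
            mean(co$age_at_dx) + 5)
})

test_that("with a null lifetable, survival follows the excess model exactly", {
  # distant stage only, constant excess hazard lambda = 0.5 (shape 1),
  # no covariate effects: net survival is exp(-0.5 t)
  spec <- cohort_spec(
    n = 50000, stage_mix = c(localised = 0, regional = 0, distant = 1),
    excess = list(
      localised = list(shape = 1, scale = 2, beta_age = 0, beta_male = 0),
      regional = list(shape = 1, scale = 2, beta_age = 0, beta_male = 0),
      distant = list(shape = 1, scale = 2, beta_age = 0, beta_male = 0)),
    years = c(2005L, 2006L), baseline_missing = c(-50, 0))
  co <- generate_cohort(spec, zero_lifetable(), seed = 3)
  lam <- 0.5
  for (tt in c(0.5, 1, 2, 4)) {
    surv_hat <- mean(co$time > tt)
    se <- sqrt(exp(-lam * tt) * (1 - exp(-lam * tt)) / nrow(co))
    expect_equal(surv_hat, exp(-lam * tt), tolerance = 4 * se / exp(-lam * tt))
  }
})

test_that("population and excess hazards add", {
  # constant lifetable rate + constant excess hazard: death hazard is the
  # sum, so P(death by t) = 1 - exp(-(r + lambda) t)
  rate <- 0.1
  ltc <- flat_lifetable(2005:2020, rate)
  spec <- cohort_spec(
    n = 50000, stage_mix = c(localised = 0, regional = 1, distant = 0),
    excess = list(
      localised = list(shape = 1, scale = 5, beta_age = 0, beta_male = 0),
      regional = list(shape = 1, scale = 5, beta_age = 0, beta_male = 0),
      distant = list(shape = 1, scale = 5, beta_age = 0, beta_male = 0)),
    years = c(2005L, 2005L), baseline_missing = c(-50, 0))
  co <- generate_cohort(spec, ltc, seed = 8)
  total <- rate + 1 / 5
  p2 <- 1 - exp(-total * 2)
  expect_equal(mean(co$time <= 2), p2, tolerance = 4 * sqrt(p2 / nrow(co)))
})

test_that("closed-form truth matches simulated net survival", {
  spec <- cohort_spec(n = 50000, baseline_missing = c(-50, 0))
  co <- generate_cohort(spec, zero_lifetable(), seed = 12)
  # restrict to diagnoses with at least 5 years of potential follow-up so
  # administrative censoring cannot bite before the evaluation time
  sub <- co %>%
    filter(stage_true == "regional", dx_date <= as.Date("2012-12-31"))
  tr <- true_marginal_rs(spec, "regional", sub$age_at_dx, sub$sex, t = 5)
  # with a null lifetable all deaths are excess deaths
  died <- mean(sub$time <= 5)
  expect_equal(1 - died, tr$rs_true, tolerance = 0.01)
})

test_that("cohort CSV round-trips", {
  co <- generate_cohort(cohort_spec(n = 200), test_lifetable(), seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as_tibble(back), as_tibble(co), tolerance = 1e-12)
  expect_error(read_cohort(withr::local_tempfile(fileext = ".csv")))
})
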