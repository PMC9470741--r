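stage_fit <- function(stage = "regional") {
  key <- paste0("fit_", stage)
  cached(key, {
    frame <- test_frame() %>% filter(stage_true == stage)
    fit_fpm(frame, test_lifetable(), fpm_config(), stage = stage)
  })
}

test_that("the standard population is the reference year with equal weights", {
  co <- test_cohort()
  sp <- build_standard_population(co, 2017)
  n2017 <- sum(format(co$dx_date, "%Y") == "2017")
  expect_equal(nrow(sp), n2017)
  expect_equal(unique(sp$weight), 1 / n2017)
  expect_equal(sum(sp$weight), 1, tolerance = 1e-12)
  expect_error(build_standard_population(co, 1999), "reference year")
})

test_that("marginal relative survival is a weighted average of conditionals", {
  fit <- stage_fit("regional")
  tg <- c(1, 5, 10)
  # single-row population: marginal equals the conditional prediction
  one <- tibble(age = 72, sex = "female", weight = 1)
  mc1 <- marginal_rs(fit, one, tg)
  cond <- predict(fit, tibble(age_at_dx = 72, sex = "female"), tg)
  expect_equal(mc1$estimate, cond$estimate, tolerance = 1e-12)
  # two half-weighted rows: exactly the average of the two conditionals
  two <- tibble(age = c(60, 80), sex = c("female", "male"),
                weight = c(0.5, 0.5))
  mc2 <- marginal_rs(fit, two, tg)
  conds <- predict(fit, tibble(age_at_dx = c(60, 80),
                               sex = c("female", "male")), tg)
  avg <- conds %>% group_by(time) %>% summarise(estimate = mean(estimate))
  expect_equal(mc2$estimate, avg$estimate, tolerance = 1e-12)
})

test_that("marginal excess hazard matches its defining identities", {
  fit <- stage_fit("regional")
  one <- tibble(age = 68, sex = "male", weight = 1)
  tg <- c(1, 4, 8)
  # single-row population: the conditional excess hazard
  eh1 <- marginal_eh(fit, one, tg)
  cond <- predict(fit, tibble(age_at_dx = 68, sex = "male"), tg,
                  type = "hazard")
  expect_equal(eh1$estimate, cond$estimate, tolerance = 1e-12)
  # mixed population: -(d/dt) log Rbar equals the marginal excess hazard
  sp <- build_standard_population(test_cohort())
  for (tt in c(1, 5)) {
    h <- tt * 1e-4
    Rp <- marginal_rs(fit, sp, tt + h)$estimate
    Rm <- marginal_rs(fit, sp, tt - h)$estimate
    fd <- -(log(Rp) - log(Rm)) / (2 * h)
    eh <- marginal_eh(fit, sp, tt)$estimate
    expect_equal(eh, fd, tolerance = 1e-5)
  }
})

test_that("the delta-method SE matches a parametric bootstrap", {
  fit <- stage_fit("distant")
  sp <- build_standard_population(test_cohort())
  tg <- c(1, 5)
  mc <- marginal_rs(fit, sp, tg)
  boots <- withr::with_seed(2024, {
    draws <- MASS::mvrnorm(500, fit$coef, fit$vcov)
    agg <- sp %>% group_by(age, sex) %>%
      summarise(weight = sum(weight), .groups = "drop")
    Z <- netstage:::fpm_covariates(fit$fit_info, agg$age, agg$sex)
    apply(draws, 1, function(th) {
      g <- netstage:::marginal_functional(fit, th, Z,
                                          agg$weight / sum(agg$weight),
                                          tg, "rs")
      log(-log(g))
    })
  })
  boot_se <- apply(boots, 1, sd)
  expect_equal(sqrt(mc$var_g), boot_se, tolerance = 0.1)
})

test_that("Rubin pooling satisfies its closed-form identities", {
  fit <- stage_fit("regional")
  sp <- build_standard_population(test_cohort())
  tg <- c(1, 5, 10)
  curve <- marginal_rs(fit, sp, tg)
  # identical imputations: pooled = the curve, B = 0, T = W
  pooled <- rubin_combine(list(curve, curve, curve))
  expect_equal(pooled$estimate, curve$estimate, tolerance = 1e-12)
  expect_equal(pooled$B, rep(0, 3))
  expect_equal(pooled$T_var, pooled$W)
  # two imputations: pooled g is the mean, B the two-point variance
  c2 <- curve
  c2$g <- curve$g + 0.1
  c2$estimate <- exp(-exp(c2$g))
  pooled2 <- rubin_combine(list(curve, c2))
  expect_equal(pooled2$g, curve$g + 0.05, tolerance = 1e-12)
  expect_equal(pooled2$B, rep(0.1^2 / 2, 3), tolerance = 1e-12)
  expect_equal(pooled2$T_var, pooled2$W + 1.5 * pooled2$B, tolerance = 1e-12)
  # back-transform round trip at R = 0.5 across identical imputations
  half <- curve
  half$g <- rep(log(-log(0.5)), 3)
  half$estimate <- rep(0.5, 3)
  expect_equal(rubin_combine(list(half, half))$estimate, rep(0.5, 3))
  # pooling is invariant to imputation order
  c3 <- curve; c3$g <- curve$g - 0.07
  expect_equal(rubin_combine(list(curve, c2, c3))$estimate,
               rubin_combine(list(c3, curve, c2))$estimate)
  # guard rails
  expect_warning(rubin_combine(list(curve)), "m = 1")
  cbad <- curve; cbad$time <- cbad$time + 1
  expect_error(rubin_combine(list(curve, cbad)), "grids")
})
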