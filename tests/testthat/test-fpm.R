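test_that("the restricted cubic basis is linear where it must be", {
  # two knots: a single linear column equal to x
  x <- seq(-2, 5, by = 0.25)
  B <- rcs(x, c(0, 1))
  expect_equal(ncol(B), 1L)
  expect_equal(unname(B[, 1]), x)
  # beyond the boundary knots the second difference vanishes (linearity)
  knots <- c(0, 0.7, 1.3, 2)
  right <- seq(2.5, 6, by = 0.1)
  B2 <- rcs(right, knots)
  for (j in seq_len(ncol(B2))) {
    expect_equal(max(abs(diff(diff(B2[, j])))), 0, tolerance = 1e-10)
  }
  left <- seq(-6, -0.5, by = 0.1)
  B3 <- rcs(left, knots)
  for (j in seq_len(ncol(B3))) {
    expect_equal(max(abs(diff(diff(B3[, j])))), 0, tolerance = 1e-10)
  }
  expect_error(rcs(x, c(1, 1, 2)), "increasing")
})

test_that("the analytic spline derivative matches finite differences", {
  set.seed(11)
  for (rep in 1:20) {
    knots <- sort(rnorm(sample(3:6, 1), sd = 2))
    if (min(diff(knots)) < 0.1) next
    x <- rnorm(40, sd = 3)
    h <- 1e-6
    fd <- (rcs(x + h, knots) - rcs(x - h, knots)) / (2 * h)
    expect_equal(rcs_deriv(x, knots), fd, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("default knots sit at the stated centiles of log event times", {
  set.seed(3)
  times <- rexp(1000, 0.3)
  expect_equal(default_knots(times, 1), range(log(times)))
  expect_equal(default_knots(times, 2),
               c(min(log(times)), median(log(times)), max(log(times))))
  k5 <- default_knots(times, 5)
  expect_equal(k5, c(min(log(times)),
                     unname(quantile(log(times), c(.2, .4, .6, .8))),
                     max(log(times))))
  expect_error(default_knots(c(1, 2), 5), "distinct")
})

weibull_frame <- function(n, shape, scale, seed, cens = 10) {
  withr::with_seed(seed, {
    tt <- scale * rexp(n)^(1 / shape)
    tibble(t0 = 0, t1 = pmin(tt, cens), d = as.integer(tt <= cens),
           sex = factor("female", levels = c("female", "male")),
           age_at_dx = 60L, dx_date = as.Date("2015-01-02"))
  })
}

test_that("with no expected hazard the fit recovers a Weibull exactly", {
  # all-cause Weibull data and a null lifetable: the log cumulative hazard
  # is a * log t + const, so the fitted curve must be linear in log time
  # with slope a
  shape <- 0.8
  frame <- weibull_frame(10000, shape, 5, seed = 313)
  fit <- fit_fpm(frame, zero_lifetable(),
                 fpm_config(covariates = character(0), td = FALSE))
  expect_true(fit$converged)
  # slope between t = 1 and t = 6 with a delta-method standard error
  Z <- netstage:::fpm_covariates(fit$fit_info, 60, "female")
  xa <- netstage:::fpm_design(fit$fit_info, 1, Z)$X
  xb <- netstage:::fpm_design(fit$fit_info, 6, Z)$X
  contrast <- (xb - xa) / log(6)
  slope <- drop(contrast %*% fit$coef)
  se <- sqrt(drop(contrast %*% fit$vcov %*% t(contrast)))
  expect_lt(abs(slope - shape), 3 * se)
})

test_that("a null excess hazard yields relative survival near one", {
  # simulate pure population mortality and hand the generator's own
  # lifetable to the fit: the excess hazard is zero by construction
  rate <- 0.08
  ltc <- flat_lifetable(2005:2030, rate)
  withr::with_seed(99, {
    n <- 4000
    tt <- rexp(n, rate)
    frame <- tibble(t0 = 0, t1 = pmin(tt, 10), d = as.integer(tt <= 10),
                    sex = factor("female", levels = c("female", "male")),
                    age_at_dx = 60L, dx_date = as.Date("2015-01-02"))
  })
  fit <- fit_fpm(frame, ltc,
                 fpm_config(covariates = character(0), td = FALSE))
  pred <- predict(fit, times = c(1, 5, 9), type = "survival")
  expect_true(all(pred$estimate > 0.95))
})

test_that("episode splitting leaves the likelihood unchanged", {
  lt <- test_lifetable()
  frame <- test_frame() %>%
    filter(stage_true == "regional") %>%
    slice_head(n = 2000)
  fit <- fit_fpm(frame, lt, fpm_config(), stage = "regional")
  # split every subject into two abutting intervals at the midpoint
  s <- (frame$t0 + frame$t1) / 2
  s <- pmax(s, 1e-6)
  first <- frame %>% mutate(t1 = s, d = 0L)
  second <- frame %>% mutate(t0 = s)
  split_frame <- bind_rows(first, second)
  # identical parameters give identical log likelihood (exact identity)
  ll_orig <- netstage:::fpm_loglik_frame(fit, frame, lt)
  ll_split <- netstage:::fpm_loglik_frame(fit, split_frame, lt)
  expect_equal(ll_split, ll_orig, tolerance = 1e-9)
  expect_equal(ll_orig, fit$loglik, tolerance = 1e-9)
  # refitting on the split data reaches the same maximum
  fit_split <- fit_fpm(split_frame, lt, fpm_config(), stage = "regional")
  expect_equal(fit_split$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("the analytic likelihood gradient matches finite differences", {
  lt <- test_lifetable()
  frame <- test_frame() %>%
    filter(stage_true == "distant") %>%
    slice_head(n = 800)
  fit <- fit_fpm(frame, lt, fpm_config(), stage = "distant")
  parts <- netstage:::fpm_parts(fit$fit_info, frame, lt)
  set.seed(17)
  checked <- 0
  while (checked < 5) {
    theta <- fit$coef + rnorm(length(fit$coef), 0, 0.02)
    if (!is.finite(netstage:::fpm_nll(theta, parts, kappa = 2))) next
    ga <- netstage:::fpm_ngr(theta, parts, kappa = 2)
    gn <- vapply(seq_along(theta), function(j) {
      h <- 1e-6 * (1 + abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (netstage:::fpm_nll(tp, parts, kappa = 2) -
         netstage:::fpm_nll(tm, parts, kappa = 2)) / (2 * h)
    }, numeric(1))
    expect_equal(ga, gn, tolerance = 1e-5, ignore_attr = TRUE)
    checked <- checked + 1
  }
})

test_that("the fitted objective beats its initialisation", {
  lt <- test_lifetable()
  frame <- test_frame() %>% filter(stage_true == "distant")
  fit <- fit_fpm(frame, lt, fpm_config(), stage = "distant")
  # a crude exponential start must not outscore the optimum
  parts <- netstage:::fpm_parts(fit$fit_info, frame, lt)
  theta_null <- numeric(length(fit$coef))
  theta_null[1] <- log(sum(frame$d) / sum(frame$t1 - frame$t0))
  theta_null[2] <- 1
  expect_gte(fit$loglik,
             -netstage:::fpm_nll(theta_null, parts) - 1e-8)
  # cumulative hazard is monotone over the observed range for this fit
  tg <- seq(min(frame$t1[frame$d == 1]), max(frame$t1), length.out = 200)
  ch <- predict(fit, tibble(age_at_dx = 70, sex = "female"), tg,
                type = "cumhaz")
  expect_true(all(diff(ch$estimate) > -1e-8))
})

test_that("predictions satisfy the survival-hazard identities", {
  lt <- test_lifetable()
  frame <- test_frame() %>% filter(stage_true == "regional")
  fit <- fit_fpm(frame, lt, fpm_config(), stage = "regional")
  nd <- tibble(age_at_dx = c(55, 75), sex = c("female", "male"))
  # R -> 1 as t -> 0+: sharp for the baseline-only model (its slope in log
  # time is positive, so the linear extrapolation sends Lambda to zero) ...
  wfit <- cached("wfit08", fit_fpm(weibull_frame(5000, 0.8, 5, seed = 515),
                                   zero_lifetable(),
                                   fpm_config(covariates = character(0),
                                              td = FALSE)))
  expect_gt(predict(wfit, times = 1e-6, type = "survival")$estimate, 0.9999)
  # ... and within data resolution (one day) for the covariate model
  early <- predict(fit, nd, 1 / 365.25, type = "survival")
  expect_true(all(early$estimate > 0.99))
  # continuity at an interior knot
  k <- exp(fit$fit_info$knots_time[3])
  lo <- predict(fit, nd, k * (1 - 1e-9), type = "survival")$estimate
  hi <- predict(fit, nd, k * (1 + 1e-9), type = "survival")$estimate
  expect_equal(lo, hi, tolerance = 1e-7)
  # lambda = -(d/dt) log R by central differences
  for (tt in c(0.5, 2, 5, 8)) {
    h <- tt * 1e-5
    Rp <- predict(fit, nd, tt + h, type = "survival")$estimate
    Rm <- predict(fit, nd, tt - h, type = "survival")$estimate
    fd <- -(log(Rp) - log(Rm)) / (2 * h)
    lam <- predict(fit, nd, tt, type = "hazard")$estimate
    expect_equal(lam, fd, tolerance = 1e-6)
  }
  expect_error(predict(fit, nd, c(-1, 2)), "positive")
})

test_that("fit serialisation round-trips through JSON", {
  lt <- test_lifetable()
  frame <- test_frame() %>% filter(stage_true == "distant")
  fit <- fit_fpm(frame, lt, fpm_config(), stage = "distant")
  path <- withr::local_tempfile(fileext = ".json")
  fpm_write_json(fit, path)
  back <- fpm_read_json(path)
  nd <- tibble(age_at_dx = c(50, 80), sex = c("female", "male"))
  expect_equal(predict(back, nd, c(1, 5, 10)),
               predict(fit, nd, c(1, 5, 10)), tolerance = 1e-10)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_equal(nrow(td), length(fit$coef))
  gl <- glance(fit)
  expect_true(gl$converged)
})

test_that("the baseline fit agrees with an independent spline fitter", {
  skip_if_not_installed("flexsurv")
  frame <- weibull_frame(3000, 0.9, 4, seed = 1414)
  fit <- fit_fpm(frame, zero_lifetable(),
                 fpm_config(covariates = character(0), td = FALSE))
  ext <- flexsurv::flexsurvspline(
    survival::Surv(t1, d) ~ 1, data = frame, k = 4, scale = "hazard")
  tg <- c(1, 2, 5, 9)
  ours <- predict(fit, times = tg, type = "survival")$estimate
  theirs <- summary(ext, t = tg, type = "survival", ci = FALSE,
                    tidy = TRUE)$est
  expect_equal(ours, theirs, tolerance = 0.02)
})
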