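#' Standard population for regression standardisation
#'
#' One row per subject diagnosed in the reference year (default: the last
#' diagnosis year observed), carrying age, sex and an equal weight summing
#' to 1. Every stage-specific marginal curve is standardised over the same
#' all-stages population, so stage curves are comparable.
#'
#' @param cohort A cohort tibble.
#' @param year Reference diagnosis year.
#' @return Tibble with columns `age`, `sex`, `weight`.
#' @export
build_standard_population <- function(cohort,
                                      year = max(dx_year(cohort$dx_date))) {
  rows <- cohort %>% filter(dx_year(.data$dx_date) == year)
  if (nrow(rows) == 0) {
    abort(paste0("no subjects diagnosed in reference year ", year))
  }
  tibble(age = rows$age_at_dx, sex = rows$sex,
         weight = rep(1 / nrow(rows), nrow(rows)))
}

# Weighted marginal functionals of an fpm_fit at coefficient vector theta.
# Returns a vector over tgrid; what = "rs" gives sum_i w_i R(t | x_i),
# "eh" the survivor-weighted mean excess hazard among the standardised
# population still alive.
marginal_functional <- function(fit, theta, Z, w, tgrid, what) {
  vapply(tgrid, function(tt) {
    des <- fpm_design(fit$fit_info, rep(tt, length(w)), Z)
    eta <- drop(des$X %*% theta)
    L <- exp(eta)
    R <- exp(-L)
    if (what == "rs") {
      sum(w * R)
    } else {
      lam <- L * drop(des$D %*% theta) / tt
      sum(w * R * lam) / sum(w * R)
    }
  }, numeric(1))
}

marginal_curve <- function(fit, sp, tgrid, what) {
  if (!all(c("age", "sex", "weight") %in% names(sp))) {
    abort("standard population needs age, sex, weight columns")
  }
  agg <- sp %>%
    group_by(.data$age, .data$sex) %>%
    summarise(weight = sum(.data$weight), .groups = "drop")
  w <- agg$weight / sum(agg$weight)
  Z <- fpm_covariates(fit$fit_info, agg$age, agg$sex)
  theta <- fit$coef
  est <- marginal_functional(fit, theta, Z, w, tgrid, what)
  trans <- if (what == "rs") {
    function(v) log(-log(pmin(pmax(v, 1e-12), 1 - 1e-12)))
  } else {
    function(v) log(pmax(v, 1e-300))
  }
  # delta-method variance on the transformed scale by numerical
  # differentiation of the standardised functional
  p <- length(theta)
  J <- matrix(0, p, length(tgrid))
  g0 <- trans(est)
  for (j in seq_len(p)) {
    h <- 1e-5 * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[j, ] <- (trans(marginal_functional(fit, tp, Z, w, tgrid, what)) -
                 trans(marginal_functional(fit, tm, Z, w, tgrid, what))) /
      (2 * h)
  }
  var_g <- colSums((fit$vcov %*% J) * J)
  out <- tibble(time = tgrid, estimate = est, g = g0, var_g = var_g)
  attr(out, "what") <- what
  attr(out, "stage") <- fit$stage
  class(out) <- unique(c("marginal_curve", class(out)))
  out
}

#' Marginal (standardised) relative survival from a fitted model
#'
#' Regression standardisation: `Rbar(t) = sum_i w_i R(t | x_i)` over the
#' standard population, with a pointwise delta-method variance on the
#' complementary log-log scale, obtained by numerical differentiation of
#' the standardised functional over the coefficient covariance.
#'
#' @param fit A converged `fpm_fit`.
#' @param sp A standard population from [build_standard_population()].
#' @param tgrid Positive evaluation times (years).
#' @return A `marginal_curve` tibble: `time`, `estimate`, `g` (transformed
#'   estimate), `var_g` (variance on the transformed scale).
#' @export
marginal_rs <- function(fit, sp, tgrid) marginal_curve(fit, sp, tgrid, "rs")

#' Marginal (standardised) excess hazard from a fitted model
#'
#' The survivor-weighted average excess hazard among those still alive in
#' the standardised population:
#' `sum_i w_i R(t|x_i) lambda(t|x_i) / sum_i w_i R(t|x_i)`, which satisfies
#' `lambda_bar(t) = -d/dt log Rbar(t)`. Variance on the log scale.
#'
#' @inheritParams marginal_rs
#' @return A `marginal_curve` tibble (transform scale: log).
#' @export
marginal_eh <- function(fit, sp, tgrid) marginal_curve(fit, sp, tgrid, "eh")

#' Pool marginal curves across imputations by Rubin's rules
#'
#' Pools on the transformed scale the curves carry (complementary log-log
#' for relative survival, log for excess hazard): pooled `g` is the mean,
#' `W` the mean within-imputation variance, `B` the between-imputation
#' sample variance, total variance `T = W + (1 + 1/m) B`, degrees of
#' freedom by the Barnard-Rubin small-sample formula, and the point estimate
#' and confidence limits are back-transformed. With `m = 1` the curve passes
#' through with `B = 0` and a warning.
#'
#' @param curves List of `m` `marginal_curve` tibbles on identical time
#'   grids.
#' @param conf Confidence level.
#' @return A `pooled_curve` tibble: `time`, `estimate`, `conf.low`,
#'   `conf.high`, `g`, `W`, `B`, `T_var`, `m`.
#' @export
rubin_combine <- function(curves, conf = 0.95) {
  m <- length(curves)
  if (m < 1) abort("need at least one curve")
  if (m == 1) warn("m = 1: between-imputation variance undefined, set to 0")
  what <- attr(curves[[1]], "what") %||% "rs"
  tg <- curves[[1]]$time
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$time, tg))) abort("time grids differ")
    if (any(!is.finite(cv$g)) || any(!is.finite(cv$var_g))) {
      abort("non-finite pooled inputs")
    }
  }
  G <- vapply(curves, function(cv) cv$g, numeric(length(tg)))
  Vg <- vapply(curves, function(cv) cv$var_g, numeric(length(tg)))
  G <- matrix(G, nrow = length(tg))
  Vg <- matrix(Vg, nrow = length(tg))
  gbar <- rowMeans(G)
  W <- rowMeans(Vg)
  B <- if (m > 1) apply(G, 1, var) else rep(0, length(tg))
  Tvar <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0 & m > 1,
               (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  crit <- qt(1 - (1 - conf) / 2, df)
  lo_g <- gbar - crit * sqrt(Tvar)
  hi_g <- gbar + crit * sqrt(Tvar)
  if (what == "rs") {
    inv <- function(g) exp(-exp(g))  # decreasing in g
    estimate <- inv(gbar); conf.low <- inv(hi_g); conf.high <- inv(lo_g)
  } else {
    inv <- exp
    estimate <- inv(gbar); conf.low <- inv(lo_g); conf.high <- inv(hi_g)
  }
  out <- tibble(time = tg, estimate = estimate, conf.low = conf.low,
                conf.high = conf.high, g = gbar, W = W, B = B,
                T_var = Tvar, m = m)
  attr(out, "what") <- what
  attr(out, "stage") <- attr(curves[[1]], "stage")
  class(out) <- unique(c("pooled_curve", class(out)))
  out
}

#' @export
autoplot.pooled_curve <- function(object, ...) {
  what <- attr(object, "what") %||% "rs"
  ylab <- if (what == "rs") "Marginal relative survival" else
    "Marginal excess hazard"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Years since diagnosis", y = ylab) +
    ggplot2::theme_minimal()
}
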