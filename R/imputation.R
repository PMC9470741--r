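# Risk-set table over analysis time with delayed entry: distinct event
# times, deaths d(t_j) and numbers at risk n(t_j), where a subject is at
# risk at t_j iff t0 < t_j <= t1.
risk_set_table <- function(frame) {
  stopifnot(all(c("t0", "t1", "d") %in% names(frame)))
  death_times <- frame$t1[frame$d == 1]
  et <- sort(unique(death_times))
  if (length(et) == 0) {
    return(tibble(time = numeric(0), deaths = integer(0), at_risk = integer(0)))
  }
  s0 <- sort(frame$t0)
  s1 <- sort(frame$t1)
  entered <- findInterval(et, s0, left.open = TRUE)   # #{t0 < t_j}
  exited <- findInterval(et, s1, left.open = TRUE)    # #{t1 < t_j}
  at_risk <- entered - exited
  deaths <- tabulate(match(death_times, et), nbins = length(et))
  if (any(at_risk < deaths)) abort("risk set smaller than death count")
  tibble(time = et, deaths = as.integer(deaths), at_risk = as.integer(at_risk))
}

#' Nelson-Aalen cumulative hazard at each subject's exit
#'
#' Computes `H(t) = sum_{t_j <= t} d(t_j) / n(t_j)` over the period frame's
#' delayed-entry risk sets (a subject is at risk at `t_j` iff
#' `t0 < t_j <= t1`), evaluated at each subject's own exit time `t1`. Used
#' as a covariate of the stage-imputation model.
#'
#' @param frame A [apply_period()] frame (needs `t0`, `t1`, `d`).
#' @return Numeric vector, one `H` value per row of `frame`.
#' @export
#' @examples
#' frame <- tibble::tibble(t0 = 0, t1 = c(1, 2, 3, 4), d = c(1, 0, 1, 0))
#' nelson_aalen(frame)  # H(3) = 1/4 + 1/3
nelson_aalen <- function(frame) {
  rs <- risk_set_table(frame)
  if (nrow(rs) == 0) return(rep(0, nrow(frame)))
  H <- cumsum(rs$deaths / rs$at_risk)
  idx <- findInterval(frame$t1, rs$time)  # counts event times <= t1, exactly
  ifelse(idx == 0, 0, H[pmax(idx, 1)])
}

#' Time-weighted cumulative-hazard statistic H1 at each subject's exit
#'
#' `H1(t) = sum_{t_j <= t} t_j * d(t_j) / n(t_j)`, the companion statistic
#' to [nelson_aalen()] recommended for imputation models when covariate
#' effects on the hazard vary over time; same risk-set convention.
#'
#' @inheritParams nelson_aalen
#' @return Numeric vector, one `H1` value per row of `frame`.
#' @export
h1_statistic <- function(frame) {
  rs <- risk_set_table(frame)
  if (nrow(rs) == 0) return(rep(0, nrow(frame)))
  H1 <- cumsum(rs$time * rs$deaths / rs$at_risk)
  idx <- findInterval(frame$t1, rs$time)
  ifelse(idx == 0, 0, H1[pmax(idx, 1)])
}

# Imputation design: auxiliary covariates plus cumulative-hazard statistics
# and their interactions with sex and age. Grade keeps "missing" as a level;
# the event indicator enters as a binary contrast; calendar year of
# diagnosis is categorical with all levels.
imputation_formula <- function() {
  stage_model ~ sex + age_at_dx + subsite + grade + dx_year_f + d_f +
    H + H1 + sex:H + age_at_dx:H + sex:H1 + age_at_dx:H1
}

imputation_design <- function(frame) {
  frame %>%
    mutate(H = nelson_aalen(frame),
           H1 = h1_statistic(frame),
           dx_year_f = factor(dx_year(.data$dx_date)),
           d_f = factor(.data$d, levels = c(0, 1)),
           grade = droplevels(factor(.data$grade)),
           subsite = droplevels(factor(.data$subsite)))
}

#' Multiply impute missing stage under a multinomial logistic model
#'
#' Fits a three-category multinomial logistic model of observed stage on
#' sex, age, subsite, grade (with unknown as a level), calendar year of
#' diagnosis, the event indicator, the Nelson-Aalen cumulative hazard `H`
#' and the time-weighted statistic `H1` at the subject's exit, plus
#' sex-by-`H`, age-by-`H`, sex-by-`H1` and age-by-`H1` interactions, among
#' the complete-stage rows of the period frame. For each of `m` imputations
#' a coefficient vector is drawn from the asymptotic normal sampling
#' distribution of the fit (proper multiple imputation), each missing-stage
#' subject's category probabilities are computed under the drawn
#' coefficients, and a stage is drawn.
#'
#' @param frame A period frame (from [apply_period()]); only rows of this
#'   frame are ever imputed.
#' @param m Number of imputations (default 30).
#' @param seed Integer seed; imputations are deterministic given frame +
#'   seed.
#' @param draw_params If `FALSE`, skip the coefficient draw and use the MLE
#'   for every imputation (improper MI; for diagnostics only).
#' @return An `imputation_set` list with `draws` (tibble `.imp`, `id`,
#'   `stage_imp` covering every missing-stage row), `fit` (the multinomial
#'   fit), `m` and `seed`.
#' @export
impute_stage <- function(frame, m = 30, seed = 1L, draw_params = TRUE) {
  stopifnot(all(c("stage_obs", "id") %in% names(frame)))
  des <- imputation_design(frame)
  des$stage_model <- factor(ifelse(des$stage_obs == "missing", NA,
                                   as.character(des$stage_obs)),
                            levels = stage_levels)
  complete <- des %>% filter(!is.na(.data$stage_model))
  missing_rows <- des %>% filter(is.na(.data$stage_model))
  if (any(table(complete$stage_model) == 0)) {
    absent <- stage_levels[table(complete$stage_model) == 0]
    abort(paste0("stage category absent from complete cases: ",
                 paste(absent, collapse = ", ")))
  }
  form <- imputation_formula()
  environment(form) <- environment()  # vcov() re-evaluates the call
  fit <- nnet::multinom(form, data = complete, model = TRUE,
                        trace = FALSE, maxit = 400, MaxNWts = 5000)
  if (fit$convergence != 0) {
    abort("multinomial imputation model failed to converge")
  }
  theta_hat <- as.vector(t(coef(fit)))
  V <- vcov(fit)
  if (any(!is.finite(V))) {
    abort("singular covariance in imputation model (separation?)")
  }
  if (nrow(missing_rows) == 0) {
    draws <- tidyr::expand_grid(.imp = seq_len(m),
                                id = integer(0), stage_imp = factor(
                                  character(0), levels = stage_levels))
    return(structure(list(draws = draws, fit = fit, m = m, seed = seed),
                     class = "imputation_set"))
  }
  Terms <- delete.response(terms(fit))
  X <- model.matrix(Terms, data = missing_rows, xlev = fit$xlevels)
  p <- ncol(X)
  draws <- with_seed(seed, {
    purrr::map_dfr(seq_len(m), function(i) {
      theta <- if (draw_params) {
        MASS::mvrnorm(1, theta_hat, V)
      } else {
        theta_hat
      }
      B <- matrix(theta, nrow = 2, byrow = TRUE)  # rows: regional, distant
      eta <- X %*% t(B)
      pr <- cbind(1, exp(eta))
      pr <- pr / rowSums(pr)
      u <- runif(nrow(pr))
      k <- 1L + (u > pr[, 1]) + (u > pr[, 1] + pr[, 2])
      tibble(.imp = i, id = missing_rows$id,
             stage_imp = factor(stage_levels[k], levels = stage_levels))
    })
  })
  structure(list(draws = draws, fit = fit, m = m, seed = seed),
            class = "imputation_set")
}

#' Partition missing-stage subjects under an imputation stress condition
#'
#' The four conditions confine strong assumptions about historical missing
#' stage to diagnoses before a boundary `B` (`prewindow_start` when the
#' pre-window is used, otherwise `window_start`):
#' * condition 1 -- impute every missing-stage subject, regardless of `B`;
#' * condition 2 -- impute on/after `B`; complete-case (exclude) before `B`;
#' * condition 3 -- impute on/after `B`; assume localised before `B`;
#' * condition 4 -- impute on/after `B`; assume distant before `B`.
#'
#' @param frame A period frame.
#' @param condition Integer 1--4.
#' @param use_prewindow Logical; whether the pre-window shields diagnoses
#'   from the condition.
#' @param pspec The [period_spec()] (defaults to the one recorded on
#'   `frame`).
#' @return `frame` with a `disposition` column: `observed`, `to_impute`,
#'   `to_exclude`, `to_assign_localised` or `to_assign_distant`.
#' @export
apply_condition <- function(frame, condition, use_prewindow = TRUE,
                            pspec = attr(frame, "period_spec")) {
  if (!condition %in% 1:4) abort("condition must be 1, 2, 3 or 4")
  if (is.null(pspec)) abort("no period_spec available; pass pspec")
  boundary <- if (use_prewindow) pspec$prewindow_start else pspec$window_start
  miss <- frame$stage_obs == "missing"
  before <- frame$dx_date < boundary
  disposition <- rep("observed", nrow(frame))
  if (condition == 1) {
    disposition[miss] <- "to_impute"
  } else {
    disposition[miss & !before] <- "to_impute"
    disposition[miss & before] <- switch(condition - 1,
                                         "to_exclude",
                                         "to_assign_localised",
                                         "to_assign_distant")
  }
  frame$disposition <- factor(disposition,
                              levels = c("observed", "to_impute",
                                         "to_exclude", "to_assign_localised",
                                         "to_assign_distant"))
  frame
}

#' Resolve a condition into m completed analysis frames
#'
#' Combines a disposition partition ([apply_condition()]) with imputed stage
#' draws ([impute_stage()]) into a long tibble of completed frames: excluded
#' rows are dropped, assigned rows receive the assumed stage, imputed rows
#' receive the draw of each imputation, observed rows keep their observed
#' stage. All non-stage columns are passed through untouched.
#'
#' @param frame A period frame with a `disposition` column.
#' @param imputations An `imputation_set` from [impute_stage()].
#' @return Long tibble with columns `.imp` (1..m) and `stage` (the analysis
#'   stage) ahead of the frame's columns.
#' @export
condition_frames <- function(frame, imputations) {
  stopifnot("disposition" %in% names(frame))
  m <- imputations$m
  kept <- frame %>% filter(.data$disposition != "to_exclude")
  base_stage <- dplyr::case_when(
    kept$disposition == "to_assign_localised" ~ "localised",
    kept$disposition == "to_assign_distant" ~ "distant",
    kept$disposition == "observed" ~ as.character(kept$stage_obs),
    TRUE ~ NA_character_)
  purrr::map_dfr(seq_len(m), function(i) {
    stage <- base_stage
    need <- which(kept$disposition == "to_impute")
    if (length(need) > 0) {
      imp_i <- imputations$draws %>% filter(.data$.imp == i)
      stage[need] <- as.character(
        imp_i$stage_imp[match(kept$id[need], imp_i$id)])
    }
    if (anyNA(stage)) abort("unresolved stage after imputation")
    dplyr::bind_cols(tibble(.imp = i,
                            stage = factor(stage, levels = stage_levels)),
                     as_tibble(kept))
  })
}
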