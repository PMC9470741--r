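#' Configuration of a full simulated imputation experiment
#'
#' Bundles every component specification: the synthetic cohort, the
#' missingness mechanism, the period window, the excess-hazard model, the
#' imputation conditions to run (1--4, each with or without the pre-window),
#' the number of imputations, the evaluation grid and the master seed.
#' Child seeds are derived per pipeline stage with [derive_seed()], so the
#' whole experiment is deterministic given the master seed.
#'
#' @param cohort A [cohort_spec()].
#' @param missingness A [missingness_spec()].
#' @param period A [period_spec()].
#' @param fpm An [fpm_config()].
#' @param conditions Integer subset of 1--4.
#' @param prewindow Logical vector of pre-window settings to run.
#' @param m Number of imputations.
#' @param tgrid Time grid for the pooled curves.
#' @param summary_times Times reported in the summary table.
#' @param std_year Reference diagnosis year for standardisation (`NULL` =
#'   last cohort diagnosis year).
#' @param reference Logical; also compute the full-data (true-stage) model
#'   fit and the Pohar-Perme estimate (default `TRUE`).
#' @param seed Master seed.
#' @param outdir Output directory for CSV/JSON artefacts (`NULL` = none).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              missingness = missingness_spec(),
                              period = period_spec(),
                              fpm = fpm_config(),
                              conditions = 1:4,
                              prewindow = c(TRUE, FALSE),
                              m = 30,
                              tgrid = c(seq(0.5, 10, by = 0.5)),
                              summary_times = c(1, 5, 10),
                              std_year = NULL,
                              reference = TRUE,
                              seed = 1L,
                              outdir = NULL) {
  if (length(conditions) == 0 || !all(conditions %in% 1:4)) {
    abort("conditions must be a non-empty subset of 1:4")
  }
  structure(list(cohort = cohort, missingness = missingness, period = period,
                 fpm = fpm, conditions = sort(unique(as.integer(conditions))),
                 prewindow = unique(prewindow), m = as.integer(m),
                 tgrid = sort(unique(c(tgrid, summary_times))),
                 summary_times = summary_times, std_year = std_year,
                 reference = isTRUE(reference),
                 seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' Serialises the scalar fields of each component spec; matrices (grade and
#' subsite mixing) round-trip as lists of rows.
#'
#' @param path YAML file path.
#' @param cfg An [experiment_config()].
#' @return `read_experiment_config()` returns an `experiment_config`.
#' @export
write_experiment_config <- function(cfg, path) {
  ser <- rapply(unclass(cfg), function(x) {
    if (inherits(x, "Date")) as.character(x) else x
  }, how = "replace")
  mat_to_rows <- function(m) {
    rows <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
    names(rows) <- rownames(m)
    rows
  }
  ser$cohort$grade_probs <- mat_to_rows(cfg$cohort$grade_probs)
  ser$cohort$subsite_probs <- mat_to_rows(cfg$cohort$subsite_probs)
  # named vectors must round-trip as YAML maps, not bare sequences
  ser$cohort$stage_mix <- as.list(cfg$cohort$stage_mix)
  ser$cohort$age_mean <- as.list(cfg$cohort$age_mean)
  ser$cohort$age_sd <- as.list(cfg$cohort$age_sd)
  ser$missingness$offset <- as.list(cfg$missingness$offset)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  co <- raw$cohort
  cohort <- cohort_spec(
    n = co$n, years = unlist(co$years),
    stage_mix = unlist(co$stage_mix), p_female = co$p_female,
    age_mean = unlist(co$age_mean), age_sd = unlist(co$age_sd),
    age_range = unlist(co$age_range),
    excess = co$excess, age_ref = co$age_ref,
    grade_probs = do.call(rbind, lapply(co$grade_probs, unlist)),
    subsite_probs = do.call(rbind, lapply(co$subsite_probs, unlist)),
    baseline_missing = unlist(co$baseline_missing),
    censor_date = co$censor_date, seed = co$seed)
  mi <- raw$missingness
  missingness <- missingness_spec(
    regional_base = mi$regional_base, increment = mi$increment,
    anchor_year = mi$anchor_year, earliest_year = mi$earliest_year,
    offset_distant = mi$offset[["distant"]],
    offset_localised = mi$offset[["localised"]], recent_p = mi$recent_p)
  pd <- raw$period
  period <- period_spec(window_start = pd$window_start,
                        window_end = pd$window_end,
                        prewindow_start = pd$prewindow_start,
                        max_followup = pd$max_followup)
  fp <- raw$fpm
  fpm <- fpm_config(baseline_df = fp$baseline_df, age_df = fp$age_df,
                    age_tail_pct = unlist(fp$age_tail_pct),
                    td_df = fp$td_df, covariates = unlist(fp$covariates),
                    td = fp$td, maxit = fp$maxit, reltol = fp$reltol,
                    hazard_floor = fp$hazard_floor)
  experiment_config(cohort = cohort, missingness = missingness,
                    period = period, fpm = fpm,
                    conditions = unlist(raw$conditions),
                    prewindow = unlist(raw$prewindow), m = raw$m,
                    tgrid = unlist(raw$tgrid),
                    summary_times = unlist(raw$summary_times),
                    std_year = raw$std_year, seed = raw$seed,
                    outdir = raw$outdir)
}

# Fit the three stage models on one completed frame and return pooled-ready
# marginal curves per stage.
fit_stage_curves <- function(frame_completed, lt, cfg, sp, tgrid) {
  purrr::map(stage_levels, function(st) {
    sub <- frame_completed %>% filter(.data$stage == st)
    fit <- fit_fpm(sub, lt, cfg$fpm, stage = st)
    marginal_rs(fit, sp, tgrid)
  }) %>% setNames(stage_levels)
}

#' Run the full simulated imputation experiment
#'
#' Simulates a registry cohort, injects the stage-missingness mechanism,
#' builds the period frame, imputes stage once (shared across conditions),
#' then for every requested (condition, pre-window) cell resolves the
#' condition, fits a flexible parametric excess-hazard model per stage and
#' per imputation, standardises to the reference-year age/sex distribution,
#' and pools with Rubin's rules. Reference quantities computed alongside:
#' the full-data (true-stage) model fit, the Pohar-Perme non-parametric
#' estimate per true stage, and the generator's closed-form truth. A failed
#' cell (e.g. a non-converged fit) is recorded and does not abort the rest.
#'
#' @param cfg An [experiment_config()].
#' @param lt Optional [lifetable()]; default is a synthetic Gompertz table
#'   covering the cohort span.
#' @param cohort Optional pre-built cohort (with `stage_true`); default is
#'   generated from `cfg$cohort`.
#' @return An `experiment_result` list: `curves` (pooled tibble per
#'   condition x pre-window x stage x time), `summary` (at
#'   `cfg$summary_times`, joined with reference, Pohar-Perme and truth),
#'   `reference`, `pp`, `truth`, `failures`, `counts` (row counts through
#'   the pipeline) and `meta`.
#' @export
run_experiment <- function(cfg, lt = NULL, cohort = NULL) {
  t_start <- Sys.time()
  if (is.null(lt)) {
    span <- cfg$cohort$years[1]:(cfg$cohort$years[2] +
                                   ceiling(cfg$period$max_followup) + 1)
    lt <- synth_lifetable(span)
  }
  if (is.null(cohort)) {
    cohort <- generate_cohort(cfg$cohort, lt,
                              seed = derive_seed(cfg$seed, "cohort"))
  }
  cohort_miss <- apply_missingness(cohort, cfg$missingness,
                                   seed = derive_seed(cfg$seed, "missingness"))
  frame <- apply_period(cohort_miss, cfg$period)
  imputations <- impute_stage(frame, m = cfg$m,
                              seed = derive_seed(cfg$seed, "imputation"))
  std_year <- cfg$std_year %||% max(dx_year(cohort$dx_date))
  sp <- build_standard_population(cohort, std_year)
  counts <- tibble(step = c("cohort", "period_frame", "missing_in_frame"),
                   rows = c(nrow(cohort), nrow(frame),
                            sum(frame$stage_obs == "missing")))

  cells <- tidyr::expand_grid(condition = cfg$conditions,
                              prewindow = cfg$prewindow)
  failures <- list()
  curves <- purrr::pmap_dfr(cells, function(condition, prewindow) {
    part <- apply_condition(frame, condition, prewindow, cfg$period)
    completed <- condition_frames(part, imputations)
    purrr::map_dfr(stage_levels, function(st) {
      res <- tryCatch({
        per_imp <- purrr::map(seq_len(cfg$m), function(i) {
          sub <- completed %>%
            filter(.data$.imp == i, .data$stage == st)
          fit <- fit_fpm(sub, lt, cfg$fpm, stage = st)
          marginal_rs(fit, sp, cfg$tgrid)
        })
        pooled <- rubin_combine(per_imp)
        as_tibble(pooled) %>%
          mutate(condition = condition, prewindow = prewindow, stage = st,
                 .before = 1)
      }, error = function(e) {
        failures[[length(failures) + 1]] <<- tibble(
          condition = condition, prewindow = prewindow, stage = st,
          message = conditionMessage(e))
        NULL
      })
      res
    })
  })

  # full-data reference: true stage, no imputation
  frame_truth <- frame %>% mutate(stage = .data$stage_true)
  want_ref <- cfg$reference %||% TRUE
  empty_ref <- tidyr::crossing(stage = stage_levels, time = cfg$tgrid) %>%
    mutate(estimate = NA_real_, g = NA_real_, var_g = NA_real_)
  reference <- if (!want_ref) empty_ref else
    purrr::map_dfr(stage_levels, function(st) {
    tryCatch({
      sub <- frame_truth %>% filter(.data$stage == st)
      fit <- fit_fpm(sub, lt, cfg$fpm, stage = st)
      mc <- marginal_rs(fit, sp, cfg$tgrid)
      as_tibble(mc) %>% mutate(stage = st, .before = 1)
    }, error = function(e) {
      failures[[length(failures) + 1]] <<- tibble(
        condition = NA_integer_, prewindow = NA, stage = st,
        message = paste("reference:", conditionMessage(e)))
      tibble(stage = st, time = cfg$tgrid, estimate = NA_real_,
             g = NA_real_, var_g = NA_real_)
    })
  })

  empty_pp <- tidyr::crossing(stage = stage_levels,
                              time = cfg$summary_times) %>%
    mutate(net_surv = NA_real_, var = NA_real_)
  pp <- if (!want_ref) empty_pp else
    purrr::map_dfr(stage_levels, function(st) {
    tryCatch({
      sub <- frame_truth %>% filter(.data$stage == st)
      est <- pohar_perme(sub, lt, tgrid = cfg$summary_times,
                         std_ages = sp$age)
      est$standardised %>% mutate(stage = st, .before = 1)
    }, error = function(e) {
      failures[[length(failures) + 1]] <<- tibble(
        condition = NA_integer_, prewindow = NA, stage = st,
        message = paste("pohar_perme:", conditionMessage(e)))
      tibble(stage = st, time = cfg$summary_times, net_surv = NA_real_,
             var = NA_real_)
    })
  })

  truth <- purrr::map_dfr(stage_levels, function(st) {
    tr <- true_marginal_rs(cfg$cohort, st, sp$age, sp$sex, sp$weight,
                           cfg$tgrid)
    tr %>% mutate(stage = st, .before = 1)
  })

  summary_tbl <- curves %>%
    filter(.data$time %in% cfg$summary_times) %>%
    select("condition", "prewindow", "stage", "time", "estimate",
           "conf.low", "conf.high") %>%
    left_join(reference %>%
                select("stage", "time", reference = "estimate"),
              by = c("stage", "time")) %>%
    left_join(pp %>% select("stage", "time", pp = "net_surv"),
              by = c("stage", "time")) %>%
    left_join(truth %>% rename(truth = "rs_true"),
              by = c("stage", "time"))

  result <- structure(list(
    curves = curves, summary = summary_tbl, reference = reference,
    pp = pp, truth = truth,
    failures = if (length(failures) > 0) bind_rows(failures) else
      tibble(condition = integer(0), prewindow = logical(0),
             stage = character(0), message = character(0)),
    counts = counts,
    meta = list(seed = cfg$seed, m = cfg$m, n = cfg$cohort$n,
                config_hash = rlang::hash(unclass(cfg)),
                elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                units = "secs")))),
    class = "experiment_result")
  if (!is.null(cfg$outdir)) {
    write_experiment_result(result, cfg$outdir)
  }
  result
}

#' Deviation of each condition's estimates from the full-data reference
#'
#' Signed and absolute deviation of the pooled marginal relative survival
#' from the full-data (true-stage) estimate and from the generator's
#' closed-form truth, at the summary times.
#'
#' @param result An `experiment_result`.
#' @return Tibble with one row per condition x pre-window x stage x time.
#' @export
compare_to_truth <- function(result) {
  result$summary %>%
    mutate(dev_reference = .data$estimate - .data$reference,
           abs_dev_reference = abs(.data$estimate - .data$reference),
           dev_truth = .data$estimate - .data$truth,
           abs_dev_truth = abs(.data$estimate - .data$truth))
}

#' Write experiment artefacts (CSV + JSON summary) to a directory
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$curves, file.path(dir, "pooled_curves.csv"))
  readr::write_csv(result$summary, file.path(dir, "summary.csv"))
  readr::write_csv(result$reference, file.path(dir, "reference_curves.csv"))
  readr::write_csv(result$pp, file.path(dir, "pohar_perme.csv"))
  readr::write_csv(compare_to_truth(result),
                   file.path(dir, "comparison.csv"))
  jsonlite::write_json(
    list(meta = result$meta, counts = result$counts,
         failures = result$failures),
    file.path(dir, "experiment.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Simulated imputation experiment\n")
  cat(sprintf("  cohort n = %d, m = %d, seed = %d, %.1f s\n",
              x$meta$n, x$meta$m, x$meta$seed, x$meta$elapsed_s))
  cat(sprintf("  cells: %d, failures: %d\n",
              nrow(dplyr::distinct(x$curves, .data$condition,
                                   .data$prewindow)),
              nrow(x$failures)))
  print(x$summary %>% filter(.data$time == max(.data$time)))
  invisible(x)
}

#' @export
autoplot.experiment_result <- function(object, ...) {
  df <- object$curves %>%
    mutate(condition = factor(.data$condition),
           prewindow = ifelse(.data$prewindow, "with pre-window",
                              "without pre-window"))
  ref <- tidyr::crossing(prewindow = unique(df$prewindow),
                         object$reference)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = ref, ggplot2::aes(colour = NULL),
                       linetype = "dashed") +
    ggplot2::facet_grid(stage ~ prewindow) +
    ggplot2::labs(x = "Years since diagnosis",
                  y = "Marginal relative survival",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}
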