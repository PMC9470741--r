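#' Period-analysis window specification
#'
#' Defines the calendar window whose person-time enters the analysis (via
#' delayed entry), the pre-window immediately before it in which stage
#' recording is assumed sufficiently complete, and the follow-up cap.
#' Defaults: period window 2015-01-01 through 2017-12-31 (inclusive),
#' pre-window starting 2012-01-01, follow-up capped at 10 years.
#'
#' @param window_start,window_end First and last calendar day of the period
#'   window (`window_end` inclusive: exits are allowed through its end).
#' @param prewindow_start First day of the pre-window
#'   (`prewindow_start <= window_start`).
#' @param max_followup Follow-up cap in years since diagnosis.
#' @return A `period_spec` list.
#' @export
period_spec <- function(window_start = as.Date("2015-01-01"),
                        window_end = as.Date("2017-12-31"),
                        prewindow_start = as.Date("2012-01-01"),
                        max_followup = 10) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  prewindow_start <- as.Date(prewindow_start)
  if (!(prewindow_start <= window_start && window_start < window_end)) {
    abort("need prewindow_start <= window_start < window_end")
  }
  if (max_followup <= 0) abort("max_followup must be positive")
  structure(list(window_start = window_start, window_end = window_end,
                 prewindow_start = prewindow_start,
                 max_followup = max_followup),
            class = "period_spec")
}

#' Build the period-analysis risk set with delayed entry
#'
#' Converts a cohort into a period frame: each subject enters analysis time
#' (years since diagnosis, days/365.25) at
#' `t0 = max(0, window_start - dx_date)` and exits at
#' `t1 = min(time, window_end + 1 day - dx_date, max_followup)`. Subjects
#' whose follow-up does not overlap the window (`t1 <= t0`) are dropped --
#' e.g. a subject censored in 2013 never reaches the 2015--2017 window.
#' `d = 1` only when the subject's death time equals `t1`: deaths exactly at
#' the follow-up cap are kept as events, deaths after the window end are
#' converted to censoring at the window boundary. `era` classifies the
#' diagnosis date against the pre-window (`in_window`, `pre_window`,
#' `pre_prewindow`).
#'
#' @param cohort Cohort tibble (must contain `dx_date`, `time`, `event`;
#'   `time > 0` is required and validated).
#' @param spec A [period_spec()].
#' @return A `period_frame` tibble: the retained cohort rows plus `t0`, `t1`,
#'   `d` and `era`.
#' @export
#' @examples
#' lt <- synth_lifetable(2005:2030)
#' frame <- apply_period(generate_cohort(cohort_spec(n = 2000), lt),
#'                       period_spec())
#' dplyr::count(frame, era)
apply_period <- function(cohort, spec = period_spec()) {
  stopifnot(all(c("dx_date", "time", "event") %in% names(cohort)))
  if (any(cohort$time <= 0)) {
    abort("subjects with non-positive follow-up time are invalid input")
  }
  t_entry <- as.numeric(spec$window_start - cohort$dx_date) / 365.25
  t_wend <- as.numeric(spec$window_end + 1 - cohort$dx_date) / 365.25
  t0 <- pmax(0, t_entry)
  t1 <- pmin(cohort$time, t_wend, spec$max_followup)
  d <- as.integer(cohort$event == 1 & cohort$time <= t1 + 1e-12)
  era <- dplyr::case_when(
    cohort$dx_date >= spec$window_start ~ "in_window",
    cohort$dx_date >= spec$prewindow_start ~ "pre_window",
    TRUE ~ "pre_prewindow")
  out <- cohort %>%
    mutate(t0 = t0, t1 = t1, d = d,
           era = factor(era, levels = c("in_window", "pre_window",
                                        "pre_prewindow"))) %>%
    filter(.data$t1 > .data$t0)
  class(out) <- unique(c("period_frame", class(out)))
  attr(out, "period_spec") <- spec
  out
}
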