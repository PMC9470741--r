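#' Specification of the calendar- and stage-conditional missingness mechanism
#'
#' Parameterises the artificial stage-missingness mechanism used to stress
#' the imputation pipeline. For diagnoses up to `anchor_year` the removal
#' probability for regional stage is `regional_base` at the anchor year and
#' grows by `increment` for every earlier calendar year; distant-stage
#' subjects are `offset` more likely and localised-stage subjects `offset`
#' less likely to be removed than regional subjects diagnosed in the same
#' year. For diagnoses in later years a single uniform probability
#' `recent_p` applies, unconditional on stage and year. With the defaults the
#' regional probability runs 0.35 (2011) up to 0.65 (2005), distant reaches
#' 0.72 in 2005, localised is 0.28 in 2011, and 0.20 applies to 2012--2017.
#'
#' @param regional_base Removal probability for regional stage in the anchor
#'   year.
#' @param increment Added probability per calendar year before the anchor
#'   year (`>= 0`).
#' @param anchor_year Last calendar year of the conditional mechanism.
#' @param earliest_year First year the conditional ramp is intended to cover
#'   (informational; earlier years keep extrapolating the ramp).
#' @param offset_distant,offset_localised Stage offsets relative to regional.
#' @param recent_p Uniform removal probability applied to diagnoses after
#'   `anchor_year`.
#' @return A `missingness_spec` list.
#' @export
missingness_spec <- function(regional_base = 0.35, increment = 0.05,
                             anchor_year = 2011L, earliest_year = 2005L,
                             offset_distant = 0.07, offset_localised = -0.07,
                             recent_p = 0.20) {
  if (increment < 0) abort("increment must be non-negative")
  spec <- list(regional_base = regional_base, increment = increment,
               anchor_year = as.integer(anchor_year),
               earliest_year = as.integer(earliest_year),
               offset = c(localised = offset_localised, regional = 0,
                          distant = offset_distant),
               recent_p = recent_p)
  structure(spec, class = "missingness_spec")
}

#' Removal probability of the missingness mechanism
#'
#' @param spec A [missingness_spec()].
#' @param stage_true True stage ("localised", "regional" or "distant");
#'   vectorised with `year`.
#' @param year Integer calendar year of diagnosis.
#' @return Probability vector, clamped to `[0, 1]` with a warning if
#'   clamping occurred.
#' @export
#' @examples
#' spec <- missingness_spec()
#' removal_probability(spec, "regional", 2011) # 0.35
#' removal_probability(spec, "distant", 2005)  # 0.72
#' removal_probability(spec, "localised", 2014) # 0.20
removal_probability <- function(spec, stage_true, year) {
  stage_true <- as.character(stage_true)
  if (!all(stage_true %in% stage_levels)) {
    abort("stage_true must be localised/regional/distant")
  }
  n <- max(length(stage_true), length(year))
  stage_true <- rep_len(stage_true, n)
  year <- rep_len(as.integer(year), n)
  p <- ifelse(year <= spec$anchor_year,
              spec$regional_base +
                spec$increment * (spec$anchor_year - year) +
                spec$offset[stage_true],
              spec$recent_p)
  p <- unname(p)
  if (any(p < 0 | p > 1)) {
    warn("removal probabilities clamped to [0, 1]")
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

#' Artificially remove stage information from a cohort
#'
#' Every subject whose observed stage is not already missing has it set to
#' missing independently, with probability
#' `removal_probability(spec, stage_true, year(dx_date))`. The true stage is
#' untouched, so downstream estimates can always be compared against truth.
#' Already-missing subjects are never re-drawn (and never resurrected).
#'
#' @param cohort A cohort tibble with `stage_true`, `stage_obs`, `dx_date`.
#' @param spec A [missingness_spec()].
#' @param seed Integer seed; the result is deterministic given cohort + seed.
#' @param exact Logical; if `TRUE`, remove an exact per-(stage, year) count
#'   `round(p * n_cell)` instead of independent Bernoulli draws.
#' @return The cohort with updated `stage_obs`.
#' @export
apply_missingness <- function(cohort, spec, seed = 1L, exact = FALSE) {
  stopifnot(all(c("stage_true", "stage_obs", "dx_date") %in% names(cohort)))
  p <- removal_probability(spec, as.character(cohort$stage_true),
                           dx_year(cohort$dx_date))
  eligible <- cohort$stage_obs != "missing"
  with_seed(seed, {
    if (exact) {
      cell <- paste(cohort$stage_true, dx_year(cohort$dx_date))
      remove <- rep(FALSE, nrow(cohort))
      for (cl in unique(cell[eligible])) {
        idx <- which(eligible & cell == cl)
        k <- round(p[idx[1]] * length(idx))
        remove[idx[sample.int(length(idx), k)]] <- TRUE
      }
    } else {
      remove <- eligible & runif(nrow(cohort)) < p
    }
    cohort$stage_obs[remove] <- "missing"
  })
  cohort
}
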