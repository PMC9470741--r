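#' Population lifetables of expected mortality rates
#'
#' A lifetable holds all-cause expected mortality rates per person-year,
#' stratified by sex, calendar year and single year of age (0--99). It is the
#' background-hazard component of every relative-survival quantity in the
#' package: the excess-hazard model likelihood, the Pohar-Perme weights and
#' the synthetic-cohort generator all query it along the demographic diagonal
#' (attained age and attained calendar year advancing together).
#'
#' Conventions, applied everywhere:
#' * fractional attained ages and calendar years map to integer cells by
#'   `floor()`; cells are half-open `[a, a + 1)`;
#' * attained ages of 99 or more use the age-99 rate (the registry convention
#'   of carrying the last rate over for as many years as required);
#' * calendar years beyond the table's last year reuse the last year's rates
#'   (follow-up can outrun published lifetables); years before the first
#'   tabulated year are an error.
#'
#' @param df A data frame with columns `sex` ("female"/"male"), `year`
#'   (integer), `age` (integer 0--99) and `rate` (expected mortality rate per
#'   person-year), one row per cell, ages 0--99 complete for every
#'   `(sex, year)` present.
#' @return A `lifetable` tibble.
#' @seealso [expected_rate()], [expected_cumhaz()], [synth_lifetable()],
#'   [read_lifetable()]
#' @export
lifetable <- function(df) {
  df <- as_tibble(df)
  required <- c("sex", "year", "age", "rate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("lifetable is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df %>%
    mutate(sex = as.character(.data$sex),
           year = as.integer(.data$year),
           age = as.integer(.data$age),
           rate = as.numeric(.data$rate)) %>%
    arrange(.data$sex, .data$year, .data$age)
  if (!all(df$sex %in% sex_levels)) {
    abort("lifetable sex must be 'female' or 'male'")
  }
  if (any(!is.finite(df$rate)) || any(df$rate < 0)) {
    abort("lifetable rates must be finite and non-negative")
  }
  if (any(df$age < 0 | df$age > 99)) {
    abort("lifetable ages must lie in 0..99")
  }
  cells <- df %>% count(.data$sex, .data$year)
  if (any(cells$n != 100)) {
    bad <- cells %>% filter(.data$n != 100)
    abort(paste0("lifetable must tabulate ages 0..99 for every (sex, year); ",
                 "incomplete: ", paste0(bad$sex, "/", bad$year, collapse = ", ")))
  }
  if (anyDuplicated(df[c("sex", "year", "age")]) > 0) {
    abort("duplicated (sex, year, age) cells in lifetable")
  }
  structure(df, class = c("lifetable", class(df)))
}

# Dense [sex, year, age] rate array for O(1) vectorised lookup.
lt_array <- function(lt) {
  years <- sort(unique(lt$year))
  if (!identical(years, seq(min(years), max(years)))) {
    abort("lifetable calendar years must be contiguous")
  }
  arr <- array(NA_real_, dim = c(2, length(years), 100),
               dimnames = list(sex_levels, years, 0:99))
  idx <- cbind(match(lt$sex, sex_levels),
               match(lt$year, years),
               lt$age + 1L)
  arr[idx] <- lt$rate
  list(arr = arr, years = years)
}

# Vectorised raw lookup with age-99 carry-over and last-year carry-forward.
lt_rate_at <- function(la, sex_idx, year, age) {
  ymin <- la$years[1]
  ymax <- la$years[length(la$years)]
  if (any(year < ymin)) {
    bad <- min(year)
    abort(sprintf("lifetable has no rates for calendar year %d (first year is %d)",
                  as.integer(bad), as.integer(ymin)))
  }
  year <- pmin(year, ymax)
  age <- pmin(age, 99L)
  la$arr[cbind(sex_idx, year - ymin + 1L, age + 1L)]
}

#' Expected mortality rate at an attained age and calendar year
#'
#' @param lt A [lifetable()].
#' @param sex Character vector, "female" or "male".
#' @param attained_age Non-negative attained age in (possibly fractional)
#'   years; floored to the integer cell, with ages >= 99 mapped to 99.
#' @param year Integer calendar year; years after the table's last year reuse
#'   the last year, years before the first are an error naming the cell.
#' @return Numeric vector of rates per person-year.
#' @export
#' @examples
#' lt <- synth_lifetable(2005:2020)
#' expected_rate(lt, "female", 64.9, 2010)
#' expected_rate(lt, "male", 103, 2015) == expected_rate(lt, "male", 99, 2015)
expected_rate <- function(lt, sex, attained_age, year) {
  if (any(attained_age < 0)) abort("attained_age must be non-negative")
  sex_idx <- match(sex, sex_levels)
  if (anyNA(sex_idx)) abort("sex must be 'female' or 'male'")
  la <- lt_array(lt)
  n <- max(length(sex_idx), length(attained_age), length(year))
  sex_idx <- rep_len(sex_idx, n)
  age <- rep_len(as.integer(floor(attained_age)), n)
  year <- rep_len(as.integer(year), n)
  lt_rate_at(la, sex_idx, year, age)
}

# Segment decomposition of the demographic diagonal.
#
# For subject i starting at (age0_i, year0_i), the expected hazard is
# piecewise constant in time-since-start u, changing only where age0 + u or
# year0 + u crosses an integer. Returns segment boundaries (n x (3H + 1)),
# rates and lengths over horizon H whole years; zero-length segments from
# coincident boundaries are harmless.
lt_segments <- function(la, sex_idx, age0, year0, horizon) {
  n <- length(sex_idx)
  H <- as.integer(ceiling(horizon + 1e-9))
  fa <- (1 - (age0 - floor(age0))) %% 1   # first age crossing offset in (0,1]
  fy <- (1 - (year0 - floor(year0))) %% 1
  fa[fa == 0] <- 1
  fy[fy == 0] <- 1
  lo <- pmin(fa, fy)
  hi <- pmax(fa, fy)
  # boundaries per unit interval j: j, j + lo, j + hi  (j = 0..H-1), then H
  B <- matrix(0, n, 3L * H + 1L)
  for (j in seq_len(H) - 1L) {
    B[, 3L * j + 1L] <- j
    B[, 3L * j + 2L] <- j + lo
    B[, 3L * j + 3L] <- j + hi
  }
  B[, 3L * H + 1L] <- H
  du <- B[, -1L, drop = FALSE] - B[, -ncol(B), drop = FALSE]
  mid <- (B[, -1L, drop = FALSE] + B[, -ncol(B), drop = FALSE]) / 2
  S <- ncol(du)
  r <- matrix(0, n, S)
  for (s in seq_len(S)) {
    r[, s] <- lt_rate_at(la, sex_idx,
                         as.integer(floor(year0 + mid[, s])),
                         as.integer(floor(age0 + mid[, s])))
  }
  list(B = B, du = du, rate = r)
}

#' Expected cumulative hazard along the demographic diagonal
#'
#' Integrates the expected mortality rate from a subject's starting point
#' (age and calendar time at diagnosis) over `t` years of follow-up, with
#' attained age and attained calendar year advancing together. The integral
#' is computed exactly as a sum over the piecewise-constant cells the
#' diagonal crosses. Expected survival is `exp(-expected_cumhaz(...))`.
#'
#' @inheritParams expected_rate
#' @param age_at_dx Age (years, possibly fractional) at the start point.
#' @param year_at_dx Calendar time (fractional year) at the start point.
#' @param t Years since the start point, `t >= 0`. Vectorised with the other
#'   arguments.
#' @return Numeric vector of cumulative expected hazards.
#' @export
#' @examples
#' lt <- synth_lifetable(2005:2030, slope = 0)  # constant rate over age
#' expected_cumhaz(lt, "female", 60, 2010, 2) # = 2 * base_rate
expected_cumhaz <- function(lt, sex, age_at_dx, year_at_dx, t) {
  if (any(t < 0)) abort("t must be non-negative")
  sex_idx <- match(sex, sex_levels)
  if (anyNA(sex_idx)) abort("sex must be 'female' or 'male'")
  if (any(age_at_dx < 0)) abort("age_at_dx must be non-negative")
  la <- lt_array(lt)
  n <- max(length(sex_idx), length(age_at_dx), length(year_at_dx), length(t))
  sex_idx <- rep_len(sex_idx, n)
  age0 <- rep_len(age_at_dx, n)
  year0 <- rep_len(year_at_dx, n)
  t <- rep_len(t, n)
  if (all(t == 0)) return(numeric(n))
  seg <- lt_segments(la, sex_idx, age0, year0, max(t))
  # clip each segment at t and sum rate * length
  clipped <- pmax(0, pmin(seg$B[, -1L, drop = FALSE], t) -
                     pmin(seg$B[, -ncol(seg$B), drop = FALSE], t))
  rowSums(seg$rate * clipped)
}

# Inverse of the expected cumulative hazard: smallest t with C(t) = target,
# or Inf if the target is not reached before `horizon`. Exact for the
# piecewise-constant rate structure; used to simulate population deaths.
lt_invert_cumhaz <- function(lt, sex, age0, year0, target, horizon) {
  la <- lt_array(lt)
  sex_idx <- match(sex, sex_levels)
  n <- length(target)
  sex_idx <- rep_len(sex_idx, n)
  age0 <- rep_len(age0, n)
  year0 <- rep_len(year0, n)
  seg <- lt_segments(la, sex_idx, age0, year0, max(horizon))
  inc <- seg$rate * seg$du
  S <- ncol(inc)
  cum <- inc
  for (s in 2:S) cum[, s] <- cum[, s - 1L] + inc[, s]
  idx <- rowSums(cum < target) + 1L
  out <- rep(Inf, n)
  hit <- idx <= S
  if (any(hit)) {
    i <- which(hit)
    ii <- cbind(i, idx[i])
    cum_prev <- ifelse(idx[i] == 1L, 0, cum[cbind(i, pmax(idx[i] - 1L, 1L))])
    out[i] <- seg$B[ii] + (target[i] - cum_prev) / seg$rate[ii]
  }
  out
}

#' Synthesise a Gompertz-form population lifetable
#'
#' Deterministic stand-in for published population rates:
#' `rate(age) = base_rate * exp(slope * age)`, multiplied by `sex_ratio` for
#' males, with an optional deterministic proportional calendar decline of
#' `drift` per year from the first year.
#'
#' The defaults approximate recent US all-cause mortality (about 0.05 per
#' person-year for an 80-year-old woman, 1.4 times higher for men, declining
#' slowly over calendar time).
#'
#' @param years Integer vector of contiguous calendar years to tabulate.
#' @param base_rate Rate at age 0 (per person-year), `> 0`.
#' @param slope Log-rate increase per year of age, `>= 0`.
#' @param sex_ratio Multiplicative male/female rate ratio.
#' @param drift Proportional decline in rates per calendar year (0 = none).
#' @return A [lifetable()].
#' @export
#' @examples
#' lt <- synth_lifetable(2005:2020)
#' expected_rate(lt, "female", 80, 2005)  # 2.5e-5 * exp(0.095 * 80)
synth_lifetable <- function(years, base_rate = 2.5e-5, slope = 0.095,
                            sex_ratio = 1.4, drift = 0.005) {
  stopifnot(base_rate > 0, slope >= 0, sex_ratio > 0, drift >= 0, drift < 1)
  years <- sort(unique(as.integer(years)))
  grid <- expand.grid(sex = sex_levels, year = years, age = 0:99,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- base_rate * exp(slope * grid$age) *
    ifelse(grid$sex == "male", sex_ratio, 1) *
    (1 - drift)^(grid$year - years[1])
  lifetable(grid)
}

#' Constant-rate lifetable (mainly for tests and examples)
#'
#' @param years Calendar years to tabulate.
#' @param rate The single rate used in every cell (may be 0).
#' @return A [lifetable()].
#' @export
flat_lifetable <- function(years, rate = 0) {
  synth_lifetable(years, base_rate = max(rate, .Machine$double.xmin),
                  slope = 0, sex_ratio = 1, drift = 0) %>%
    mutate(rate = rate) %>%
    lifetable()
}

#' Read / write a lifetable CSV
#'
#' The schema is `sex, year, age, rate` (rate per person-year). A column
#' `prob` (annual death probability) is accepted instead of `rate` and
#' converted via `rate = -log(1 - prob)`. Schema violations raise errors
#' naming the offending rows.
#'
#' @param path File path.
#' @return `read_lifetable()` returns a [lifetable()]; `write_lifetable()`
#'   returns `path` invisibly.
#' @export
read_lifetable <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"rate" %in% names(df)) {
    if (!"prob" %in% names(df)) {
      abort("lifetable CSV needs a 'rate' or 'prob' column")
    }
    if (any(df$prob < 0 | df$prob >= 1)) {
      bad <- which(df$prob < 0 | df$prob >= 1)
      abort(paste0("prob outside [0, 1) at data row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    df$rate <- -log(1 - df$prob)
    df$prob <- NULL
  }
  for (col in c("sex", "year", "age")) {
    if (!col %in% names(df)) {
      abort(paste0("lifetable CSV is missing column '", col, "'"))
    }
  }
  bad_sex <- which(!df$sex %in% sex_levels)
  if (length(bad_sex) > 0) {
    abort(paste0("invalid sex at data row(s) ",
                 paste(head(bad_sex, 5), collapse = ", ")))
  }
  lifetable(df)
}

#' @rdname read_lifetable
#' @param lt A [lifetable()] to write.
#' @export
write_lifetable <- function(lt, path) {
  readr::write_csv(as_tibble(lt), path)
  invisible(path)
}
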