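suppressMessages({
  library(dplyr)
  library(tibble)
})

# ---- shared fixtures, built once per test run ------------------------------

.ns_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ns_cache)) {
    assign(key, force(expr), envir = .ns_cache)
  }
  get(key, envir = .ns_cache)
}

test_lifetable <- function() cached("lt", synth_lifetable(2005:2030))

zero_lifetable <- function() cached("lt0", flat_lifetable(2005:2030, 0))

# a mid-sized cohort + period frame shared by several test files
test_cohort <- function() {
  cached("cohort10k",
         generate_cohort(cohort_spec(n = 10000), test_lifetable(), seed = 99))
}

test_frame <- function() cached("frame10k", apply_period(test_cohort()))

# minimal frame constructor for risk-set statistics
toy_frame <- function(t0, t1, d) {
  tibble(t0 = t0, t1 = t1, d = d,
         sex = factor("female", levels = c("female", "male")),
         age_at_dx = 60L, dx_date = as.Date("2015-06-01"))
}

# random delayed-entry frames with ties for oracle comparisons
random_frame <- function(n) {
  t0 <- round(runif(n, 0, 3), 1)            # one-decimal grid forces ties
  t1 <- t0 + round(runif(n, 0.1, 5), 1) + 0.05
  toy_frame(t0, t1, d = rbinom(n, 1, 0.5))
}

# brute-force double-loop oracle for H and H1 on delayed-entry risk sets
oracle_H <- function(frame, weighted = FALSE) {
  et <- sort(unique(frame$t1[frame$d == 1]))
  out <- numeric(nrow(frame))
  for (i in seq_len(nrow(frame))) {
    acc <- 0
    for (tj in et) {
      if (tj <= frame$t1[i]) {
        dj <- sum(frame$d == 1 & frame$t1 == tj)
        nj <- sum(frame$t0 < tj & frame$t1 >= tj)
        acc <- acc + (if (weighted) tj else 1) * dj / nj
      }
    }
    out[i] <- acc
  }
  out
}

# single-subject cohort row used by period/imputation walk-throughs
make_subject <- function(dx, end, event) {
  tibble(id = 1L, sex = factor("female", levels = c("female", "male")),
         age_at_dx = 60L, dx_date = as.Date(dx),
         stage_true = factor("regional",
                             levels = c("localised", "regional", "distant")),
         stage_obs = factor("regional",
                            levels = c("localised", "regional", "distant",
                                       "missing")),
         grade = factor("II"), subsite = factor("C18.0"),
         time = as.numeric(as.Date(end) - as.Date(dx)) / 365.25,
         event = as.integer(event))
}

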