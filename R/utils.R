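#' Derive a reproducible child seed from a master seed and a label
#'
#' Child seeds are a deterministic hash of `(master, label)`, so adding a new
#' pipeline stage (a new label) never perturbs the draws of existing stages.
#' The result is always in `[1, 2^31 - 2]`, a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param label Character scalar naming the pipeline stage.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  s <- abs(as.numeric(master)) %% m
  for (code in utf8ToInt(label)) {
    s <- (s * 31 + code) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# Fractional calendar year of a Date: 2015.0 is 2015-01-01 00:00.
year_frac <- function(date) {
  y <- as.integer(format(date, "%Y"))
  jan1 <- as.Date(paste0(y, "-01-01"))
  y + as.numeric(date - jan1) / 365.25
}

dx_year <- function(date) as.integer(format(date, "%Y"))

# Evaluate a function under a temporary RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_levels <- c("localised", "regional", "distant")
stage_obs_levels <- c("localised", "regional", "distant", "missing")
sex_levels <- c("female", "male")
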