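#' Restricted cubic spline basis and its analytic derivative
#'
#' Standard restricted (natural) cubic spline parameterisation: with knots
#' `k_1 < ... < k_K`, the first column is `x` and column `j + 1`
#' (`j = 1..K-2`) is
#' `((x - k_j)_+^3 - l_j (x - k_1)_+^3 - (1 - l_j)(x - k_K)_+^3) / (k_K - k_1)^2`
#' with `l_j = (k_K - k_j) / (k_K - k_1)`. The basis has `K - 1` columns and
#' is exactly linear beyond the boundary knots; with 2 knots it is the single
#' linear column `x`. `rcs_deriv()` is the exact analytic derivative, used to
#' turn a fitted log cumulative hazard into a hazard.
#'
#' @param x Numeric vector of evaluation points.
#' @param knots Strictly increasing knot vector, length `>= 2`.
#' @return Matrix with `length(x)` rows and `length(knots) - 1` columns.
#' @export
rcs <- function(x, knots) {
  K <- length(knots)
  if (K < 2 || is.unsorted(knots, strictly = TRUE)) {
    abort("knots must be strictly increasing, length >= 2")
  }
  out <- matrix(0, length(x), K - 1)
  out[, 1] <- x
  if (K > 2) {
    k1 <- knots[1]; kK <- knots[K]
    norm <- (kK - k1)^2
    cube <- function(z) pmax(z, 0)^3
    for (j in 2:(K - 1)) {
      lam <- (kK - knots[j]) / (kK - k1)
      out[, j] <- (cube(x - knots[j]) - lam * cube(x - k1) -
                     (1 - lam) * cube(x - kK)) / norm
    }
  }
  colnames(out) <- paste0("rcs", seq_len(K - 1))
  out
}

#' @rdname rcs
#' @export
rcs_deriv <- function(x, knots) {
  K <- length(knots)
  if (K < 2 || is.unsorted(knots, strictly = TRUE)) {
    abort("knots must be strictly increasing, length >= 2")
  }
  out <- matrix(0, length(x), K - 1)
  out[, 1] <- 1
  if (K > 2) {
    k1 <- knots[1]; kK <- knots[K]
    norm <- (kK - k1)^2
    sq <- function(z) pmax(z, 0)^2
    for (j in 2:(K - 1)) {
      lam <- (kK - knots[j]) / (kK - k1)
      out[, j] <- 3 * (sq(x - knots[j]) - lam * sq(x - k1) -
                         (1 - lam) * sq(x - kK)) / norm
    }
  }
  colnames(out) <- paste0("rcs", seq_len(K - 1))
  out
}

#' Default knot placement on the log-time axis
#'
#' Boundary knots at the minimum and maximum of the uncensored log event
#' times; `df - 1` interior knots at equally spaced centiles (df = 5 gives
#' the 20/40/60/80 centiles, df = 2 the median).
#'
#' @param event_times Positive event (death) times.
#' @param df Spline degrees of freedom (number of basis columns), `>= 1`.
#' @return Increasing knot vector of length `df + 1` on the log scale.
#' @export
default_knots <- function(event_times, df) {
  if (df < 1) abort("df must be >= 1")
  u <- log(sort(unique(event_times[event_times > 0])))
  if (length(u) < df + 1) {
    abort(paste0("need at least ", df + 1, " distinct uncensored event times"))
  }
  interior <- if (df >= 2) {
    unname(quantile(log(event_times[event_times > 0]),
                    probs = seq_len(df - 1) / df, type = 7))
  } else {
    numeric(0)
  }
  knots <- c(min(u), interior, max(u))
  if (is.unsorted(knots, strictly = TRUE)) {
    knots <- unique(knots)
    if (length(knots) < df + 1) {
      abort("tied centiles leave too few distinct knots")
    }
  }
  knots
}

#' Configuration of the flexible parametric excess-hazard model
#'
#' @param baseline_df Degrees of freedom of the baseline log cumulative
#'   excess hazard spline in log time (default 5).
#' @param age_df Degrees of freedom of the age spline main effect (default
#'   4).
#' @param age_tail_pct Lower/upper percentiles at which the age effect is
#'   constrained to be constant (ages are winsorised there before spline
#'   evaluation; default 2 and 98).
#' @param td_df Degrees of freedom of each time-dependent effect spline
#'   (default 2); the time-dependent effect of age uses a fresh age spline
#'   with `td_df` degrees of freedom rather than the main-effect spline.
#' @param covariates Character subset of `c("age", "sex")`; empty fits a
#'   baseline-only model.
#' @param td Logical; enable time-dependent effects for each covariate.
#' @param maxit,reltol Optimiser control (quasi-Newton with analytic
#'   gradient).
#' @param hazard_floor Soft floor for the total hazard inside the log
#'   likelihood; events sitting on the floor at convergence flag the fit.
#' @return An `fpm_config` list.
#' @export
fpm_config <- function(baseline_df = 5, age_df = 4, age_tail_pct = c(2, 98),
                       td_df = 2, covariates = c("age", "sex"), td = TRUE,
                       maxit = 500, reltol = 1e-10, hazard_floor = 1e-10) {
  stopifnot(baseline_df >= 1, age_df >= 1, td_df >= 1,
            all(covariates %in% c("age", "sex")),
            age_tail_pct[1] > 0, age_tail_pct[1] < 50)
  structure(list(baseline_df = baseline_df, age_df = age_df,
                 age_tail_pct = age_tail_pct, td_df = td_df,
                 covariates = covariates, td = td, maxit = maxit,
                 reltol = reltol, hazard_floor = hazard_floor),
            class = "fpm_config")
}

# Gram-Schmidt orthogonalisation of a spline block against the intercept
# (and within itself), computed once on the fitting data and frozen as an
# upper-triangular transform; essential for the conditioning of cubic
# bases whose boundary knots can sit at extreme log times.
orth_transform <- function(M) {
  qrd <- qr(cbind(1, M))
  R <- qr.R(qrd)[seq_len(ncol(M) + 1), , drop = FALSE]
  s <- sign(diag(R))
  s[s == 0] <- 1
  R <- s * R
  backsolve(R, diag(ncol(R))) * sqrt(nrow(M))
}

orth_apply <- function(M, Tm) {
  (cbind(1, M) %*% Tm)[, -1, drop = FALSE]
}

orth_apply_deriv <- function(D, Tm) {
  (cbind(0, D) %*% Tm)[, -1, drop = FALSE]
}

# Covariate blocks for one subject set: main-effect and TD-effect columns.
fpm_covariates <- function(fit_info, age, sex) {
  Z_main <- NULL
  Z_td <- NULL
  if ("age" %in% fit_info$covariates) {
    agew <- pmin(pmax(age, fit_info$age_win[1]), fit_info$age_win[2])
    A_main <- orth_apply(rcs(agew, fit_info$knots_age_main),
                         fit_info$orth_age_main)
    colnames(A_main) <- paste0("age", seq_len(ncol(A_main)))
    Z_main <- A_main
    if (fit_info$td) {
      A_td <- orth_apply(rcs(agew, fit_info$knots_age_td),
                         fit_info$orth_age_td)
      colnames(A_td) <- paste0("age", seq_len(ncol(A_td)))
      Z_td <- A_td
    }
  }
  if ("sex" %in% fit_info$covariates) {
    male <- cbind(male = as.numeric(as.character(sex) == "male"))
    Z_main <- cbind(Z_main, male)
    if (fit_info$td) Z_td <- cbind(Z_td, male)
  }
  list(main = Z_main, td = Z_td)
}

# Full design at analysis times t for given covariate blocks.
# Returns X (for the log cumulative hazard) and D = dX/d(log t).
fpm_design <- function(fit_info, t, Z) {
  u <- log(t)
  B0 <- orth_apply(rcs(u, fit_info$knots_time), fit_info$orth_time)
  D0 <- orth_apply_deriv(rcs_deriv(u, fit_info$knots_time),
                         fit_info$orth_time)
  colnames(B0) <- colnames(D0) <- paste0("t", seq_len(ncol(B0)))
  X <- cbind(`(Intercept)` = 1, B0)
  D <- cbind(`(Intercept)` = 0, D0)
  if (!is.null(Z$main)) {
    X <- cbind(X, Z$main)
    D <- cbind(D, matrix(0, length(u), ncol(Z$main)))
  }
  if (fit_info$td && !is.null(Z$td)) {
    Btd <- orth_apply(rcs(u, fit_info$knots_td), fit_info$orth_td)
    Dtd <- orth_apply_deriv(rcs_deriv(u, fit_info$knots_td),
                            fit_info$orth_td)
    for (k in seq_len(ncol(Btd))) {
      blk <- Z$td * Btd[, k]
      dblk <- Z$td * Dtd[, k]
      colnames(blk) <- colnames(dblk) <-
        paste0("td", k, ":", colnames(Z$td))
      X <- cbind(X, blk)
      D <- cbind(D, dblk)
    }
  }
  list(X = X, D = D)
}

# Negative log likelihood and analytic gradient of the excess-hazard model.
# parts: X1, D1 (design at exit), X0 + rows0 (design at entry for t0 > 0),
# d (event flag), t1, hstar (expected rate at exit).
# The spline does not enforce a monotone cumulative hazard, so under
# delayed entry the +Lambda(t0) likelihood term can grow without bound
# through negative-hazard canyons in event-free regions of
# (time x covariate) space. Two guards:
# * parameter values with a non-positive total hazard at an event are
#   infeasible (+Inf; the line search backtracks) -- the floor only
#   protects log() numerically;
# * an admissibility penalty kappa * sum max(0, Lambda(t0) - Lambda(t1))^2
#   over subjects with delayed entry: Lambda(t0) > Lambda(t1) means a
#   survival probability above 1 over the subject's own at-risk interval,
#   which is exactly the inadmissible direction the divergence exploits.
#   At any admissible solution the penalty is identically zero, so the
#   objective coincides with the log likelihood and the estimator is the
#   unpenalised MLE. Mildly negative fitted excess hazards elsewhere are
#   allowed (and flagged), as is standard for spline excess-hazard models.
fpm_nll <- function(theta, parts, floor = 1e-10, kappa = 0) {
  eta1 <- drop(parts$X1 %*% theta)
  L1 <- exp(eta1)
  deta1 <- drop(parts$D1 %*% theta)
  lam <- L1 * deta1 / parts$t1
  htot <- parts$hstar + lam
  if (any(parts$d == 1 & htot <= floor)) return(Inf)
  ll <- sum(parts$d * log(pmax(htot, floor))) - sum(L1)
  pen <- 0
  if (length(parts$rows0) > 0) {
    L0 <- exp(drop(parts$X0 %*% theta))
    ll <- ll + sum(L0)
    pen <- kappa * sum(pmax(L0 - L1[parts$rows0], 0)^2)
  }
  -ll + pen
}

fpm_ngr <- function(theta, parts, floor = 1e-10, kappa = 0) {
  eta1 <- drop(parts$X1 %*% theta)
  L1 <- exp(eta1)
  deta1 <- drop(parts$D1 %*% theta)
  lam <- L1 * deta1 / parts$t1
  htot <- pmax(parts$hstar + lam, floor)
  w <- parts$d / htot
  g <- drop(crossprod(parts$X1, w * lam - L1)) +
    drop(crossprod(parts$D1, w * L1 / parts$t1))
  if (length(parts$rows0) > 0) {
    L0 <- exp(drop(parts$X0 %*% theta))
    m <- 2 * kappa * pmax(L0 - L1[parts$rows0], 0)
    g <- g + drop(crossprod(parts$X0, (1 - m) * L0))
    if (any(m > 0)) {
      gm <- numeric(length(L1))
      gm[parts$rows0] <- m * L1[parts$rows0]
      g <- g + drop(crossprod(parts$X1, gm))
    }
  }
  -g
}

# Assemble likelihood parts from a period frame using frozen basis info.
fpm_parts <- function(fit_info, frame, lt) {
  Z <- fpm_covariates(fit_info, frame$age_at_dx, frame$sex)
  at_exit <- fpm_design(fit_info, frame$t1, Z)
  yf <- year_frac(frame$dx_date)
  rows0 <- which(frame$t0 > 0)
  X0 <- D0 <- NULL
  tt0 <- hstar0 <- numeric(0)
  if (length(rows0) > 0) {
    Zi <- lapply(Z, function(z) if (is.null(z)) NULL else
      z[rows0, , drop = FALSE])
    at_entry <- fpm_design(fit_info, frame$t0[rows0], Zi)
    X0 <- at_entry$X
    D0 <- at_entry$D
    tt0 <- frame$t0[rows0]
    hstar0 <- expected_rate(lt, as.character(frame$sex[rows0]),
                            frame$age_at_dx[rows0] + tt0,
                            floor(yf[rows0] + tt0))
  }
  hstar <- expected_rate(lt, as.character(frame$sex),
                         frame$age_at_dx + frame$t1,
                         floor(yf + frame$t1))
  list(X1 = at_exit$X, D1 = at_exit$D, X0 = X0, D0 = D0, rows0 = rows0,
       tt0 = tt0, d = frame$d, t1 = frame$t1, hstar = hstar,
       hstar0 = hstar0)
}

# subset all design blocks to a set of columns (baseline-only passes)
fpm_parts_cols <- function(parts, cols) {
  list(X1 = parts$X1[, cols, drop = FALSE],
       D1 = parts$D1[, cols, drop = FALSE],
       X0 = if (length(parts$rows0) > 0)
         parts$X0[, cols, drop = FALSE] else NULL,
       D0 = if (length(parts$rows0) > 0)
         parts$D0[, cols, drop = FALSE] else NULL,
       rows0 = parts$rows0, tt0 = parts$tt0, d = parts$d, t1 = parts$t1,
       hstar = parts$hstar, hstar0 = parts$hstar0)
}

# largest admissibility violation: max over delayed-entry subjects of
# Lambda(t0) - Lambda(t1) (positive means survival probability > 1)
fpm_max_inadmissible <- function(theta, parts) {
  if (length(parts$rows0) == 0) return(0)
  L1 <- exp(drop(parts$X1 %*% theta))
  L0 <- exp(drop(parts$X0 %*% theta))
  max(L0 - L1[parts$rows0])
}

# smallest total hazard over all entry and exit points (diagnostic)
fpm_min_htot <- function(theta, parts) {
  eta1 <- drop(parts$X1 %*% theta)
  lam <- exp(eta1) * drop(parts$D1 %*% theta) / parts$t1
  out <- min(parts$hstar + lam)
  if (length(parts$rows0) > 0) {
    eta0 <- drop(parts$X0 %*% theta)
    lam0 <- exp(eta0) * drop(parts$D0 %*% theta) / parts$tt0
    out <- min(out, min(parts$hstar0 + lam0))
  }
  out
}

#' Fit a flexible parametric excess-hazard model for one stage
#'
#' Maximises the relative-survival likelihood
#' `sum_i d_i log(h*_i(t1_i) + lambda_i(t1_i)) - Lambda_i(t1_i) + Lambda_i(t0_i)`
#' with `log Lambda(t | x) = s0(log t) + x' beta + sum_k s_k(log t) x_k`:
#' restricted cubic splines for the baseline log cumulative excess hazard
#' (df 5 by default) and for each time-dependent effect (df 2), age entering
#' through a df-4 spline on age winsorised at its 2nd/98th percentiles (so
#' the age effect is exactly constant in the tails), and the subject's
#' expected mortality rate `h*` taken from the population lifetable at the
#' attained age and calendar year of exit. Delayed entry (`t0 > 0`) is
#' handled exactly through the `+ Lambda(t0)` term. Optimisation is
#' quasi-Newton (BFGS) with the analytic gradient, initialised from a
#' baseline-only fit; the coefficient covariance is the inverse observed
#' information at the optimum.
#'
#' @param frame A period frame restricted to a single analysis stage
#'   (columns `t0`, `t1`, `d`, `age_at_dx`, `sex`, `dx_date`).
#' @param lt A [lifetable()] covering the subjects' attained ages and years.
#' @param cfg An [fpm_config()].
#' @param stage Optional stage label stored on the fit.
#' @return An `fpm_fit` object: coefficients, covariance, knots, centring
#'   constants, log likelihood, convergence diagnostics (gradient norm,
#'   events on the hazard floor), and the fitting configuration.
#' @export
fit_fpm <- function(frame, lt, cfg = fpm_config(), stage = NA_character_) {
  stopifnot(all(c("t0", "t1", "d") %in% names(frame)))
  if (any(frame$t1 <= frame$t0) || any(frame$t0 < 0)) {
    abort("need 0 <= t0 < t1 for every subject")
  }
  if (length(cfg$covariates) > 0 &&
      !all(c("age_at_dx", "sex") %in% names(frame))) {
    abort("frame must contain age_at_dx and sex")
  }
  event_times <- frame$t1[frame$d == 1]
  knots_time <- default_knots(event_times, cfg$baseline_df)
  knots_td <- if (cfg$td) {
    c(knots_time[1],
      default_knots(event_times, cfg$td_df)[-c(1, cfg$td_df + 1)],
      knots_time[length(knots_time)])
  } else {
    NULL
  }
  fit_info <- list(covariates = cfg$covariates, td = cfg$td &&
                     length(cfg$covariates) > 0,
                   knots_time = knots_time, knots_td = knots_td)
  if ("age" %in% cfg$covariates) {
    aw <- quantile(frame$age_at_dx, probs = cfg$age_tail_pct / 100, type = 7)
    if (diff(aw) <= 0) abort("degenerate age distribution")
    fit_info$age_win <- unname(aw)
    agew <- pmin(pmax(frame$age_at_dx, aw[1]), aw[2])
    qs_main <- seq(0, 1, length.out = cfg$age_df + 1)
    fit_info$knots_age_main <- unique(unname(
      quantile(agew, probs = qs_main, type = 7)))
    qs_td <- seq(0, 1, length.out = cfg$td_df + 1)
    fit_info$knots_age_td <- unique(unname(
      quantile(agew, probs = qs_td, type = 7)))
    if (length(fit_info$knots_age_main) < 2 ||
        length(fit_info$knots_age_td) < 2) {
      abort("too few distinct ages for the age spline")
    }
    fit_info$orth_age_main <-
      orth_transform(rcs(agew, fit_info$knots_age_main))
    fit_info$orth_age_td <- orth_transform(rcs(agew, fit_info$knots_age_td))
  }
  u1 <- log(frame$t1)
  fit_info$orth_time <- orth_transform(rcs(u1, knots_time))
  if (fit_info$td) fit_info$orth_td <- orth_transform(rcs(u1, knots_td))

  parts <- fpm_parts(fit_info, frame, lt)
  p <- ncol(parts$X1)
  pb <- cfg$baseline_df + 1  # baseline block: intercept + time spline

  # initialisation: crude all-cause Nelson-Aalen cumulative hazard regressed
  # on the baseline basis, deflated to the excess scale by the crude excess
  # fraction (all-cause H overshoots the excess cumulative hazard, and a
  # too-large init can strand BFGS on the flat zero-excess plateau), then a
  # baseline-only quasi-Newton pass
  H <- nelson_aalen(frame)
  ok <- frame$d == 1 & H > 0
  theta0 <- numeric(p)
  names(theta0) <- colnames(parts$X1)
  if (sum(ok) >= pb) {
    Xb <- parts$X1[ok, seq_len(pb), drop = FALSE]
    A <- crossprod(Xb) + 1e-8 * diag(pb)  # tiny ridge for safety
    init <- tryCatch(solve(A, crossprod(Xb, log(H[ok]))),
                     error = function(e) NULL)
    if (!is.null(init)) theta0[seq_len(pb)] <- init
  }
  if (theta0[1] == 0) {
    theta0[1] <- log(max(sum(frame$d), 1) / sum(frame$t1 - frame$t0))
  }
  d_exp <- sum(parts$hstar * (frame$t1 - frame$t0))
  excess_frac <- (sum(frame$d) - d_exp) / max(sum(frame$d), 1)
  theta0[1] <- theta0[1] + log(min(1, max(0.1, excess_frac)))
  # guard feasibility of the starting point: blend towards a Weibull-like
  # shape (unit slope in log time, hazard positive everywhere) if needed
  fallback <- numeric(p)
  fallback[1] <- theta0[1]
  fallback[2] <- 1
  base_cols <- seq_len(pb)
  base_parts <- fpm_parts_cols(parts, base_cols)
  for (wmix in c(1, 0.7, 0.5, 0.3, 0.15, 0)) {
    cand <- wmix * theta0[base_cols] + (1 - wmix) * fallback[base_cols]
    if (is.finite(fpm_nll(cand, base_parts, floor = cfg$hazard_floor))) {
      theta0[base_cols] <- cand
      break
    }
  }
  ctrl <- list(maxit = cfg$maxit, reltol = cfg$reltol)
  # worst tolerated per-subject overshoot of Lambda(t0) over Lambda(t1):
  # small spline wiggles of this size are statistically harmless, and
  # forcing them to zero with a very large kappa distorts the fit
  admiss_tol <- 0.02
  kappa <- 1
  base_opt <- optim(theta0[base_cols], fpm_nll, fpm_ngr, parts = base_parts,
                    floor = cfg$hazard_floor, kappa = kappa,
                    method = "BFGS", control = ctrl)
  theta0[base_cols] <- base_opt$par

  # adaptive penalty: refit with a 10x stronger admissibility penalty
  # until no subject has Lambda(t0) > Lambda(t1) at the solution (where
  # the penalty is identically zero and the fit is the plain MLE)
  opt <- NULL
  theta_start <- theta0
  for (k in 1:6) {
    opt <- optim(theta_start, fpm_nll, fpm_ngr, parts = parts,
                 floor = cfg$hazard_floor, kappa = kappa,
                 method = "BFGS", control = ctrl)
    opt2 <- optim(opt$par, fpm_nll, fpm_ngr, parts = parts,
                  floor = cfg$hazard_floor, kappa = kappa,
                  method = "BFGS", control = ctrl)
    if (opt2$value < opt$value) opt <- opt2
    if (fpm_max_inadmissible(opt$par, parts) <= admiss_tol) break
    kappa <- kappa * 10
    theta_start <- opt$par
  }
  theta <- opt$par
  grad <- fpm_ngr(theta, parts, floor = cfg$hazard_floor, kappa = kappa)
  hess <- optimHess(theta, fpm_nll, fpm_ngr, parts = parts,
                    floor = cfg$hazard_floor, kappa = kappa)
  # a BFGS end point can be a saddle: escape along the most negative
  # curvature direction and reoptimise before giving up
  for (try in 1:3) {
    ev <- eigen(hess, symmetric = TRUE)
    if (min(ev$values) > 0) break
    v <- ev$vectors[, which.min(ev$values)]
    cand <- purrr::map(c(0.3, -0.3, 1, -1), function(s) {
      st <- theta + s * v
      if (!is.finite(fpm_nll(st, parts, floor = cfg$hazard_floor,
                             kappa = kappa))) return(NULL)
      optim(st, fpm_nll, fpm_ngr, parts = parts,
            floor = cfg$hazard_floor, kappa = kappa,
            method = "BFGS", control = ctrl)
    })
    cand <- purrr::compact(cand)
    vals <- vapply(cand, function(o) o$value, numeric(1))
    if (length(vals) == 0 || min(vals) >= opt$value - 1e-8) break
    opt <- cand[[which.min(vals)]]
    theta <- opt$par
    hess <- optimHess(theta, fpm_nll, fpm_ngr, parts = parts,
                      floor = cfg$hazard_floor, kappa = kappa)
  }
  worst_inadmissible <- fpm_max_inadmissible(theta, parts)
  clean <- worst_inadmissible <= admiss_tol
  grad <- fpm_ngr(theta, parts, floor = cfg$hazard_floor, kappa = kappa)
  # covariance from the observed information; directions that are flat to
  # numerical precision get their eigenvalues floored (a pseudo-inverse),
  # which reports them as very uncertain rather than failing the fit -- a
  # clearly negative eigenvalue is a genuine saddle and still errors
  ev <- eigen(hess, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values))) {
    abort("observed information not positive definite at the optimum")
  }
  lam_floor <- 1e-10 * max(abs(ev$values))
  V <- ev$vectors %*% (t(ev$vectors) / pmax(ev$values, lam_floor))
  if (any(diag(V) <= 0)) {
    abort("singular observed information in excess-hazard model")
  }

  # floor diagnostics at convergence
  eta1 <- drop(parts$X1 %*% theta)
  lam <- exp(eta1) * drop(parts$D1 %*% theta) / parts$t1
  on_floor <- sum(parts$d == 1 &
                    (parts$hstar + lam) < cfg$hazard_floor)
  structure(list(stage = stage, coef = theta, vcov = V,
                 loglik = -fpm_nll(theta, parts, floor = cfg$hazard_floor),
                 fit_info = fit_info, cfg = cfg,
                 n = nrow(frame), n_events = sum(frame$d),
                 gradient_norm = max(abs(grad)),
                 converged = opt$convergence == 0 && on_floor == 0 && clean,
                 optim_convergence = opt$convergence,
                 events_on_floor = on_floor, penalty_kappa = kappa,
                 admissible = clean,
                 max_inadmissible = worst_inadmissible,
                 hazard_nonnegative = fpm_min_htot(theta, parts) >= 0),
            class = "fpm_fit")
}

# Log likelihood of an existing fit's model evaluated on a (possibly
# episode-split) frame at arbitrary coefficients.
fpm_loglik_frame <- function(fit, frame, lt, theta = fit$coef) {
  parts <- fpm_parts(fit$fit_info, frame, lt)
  -fpm_nll(theta, parts, floor = fit$cfg$hazard_floor)
}

#' Predict relative survival or excess hazard from a fitted model
#'
#' Deterministic evaluation from the stored knots and coefficients:
#' `R(t | x) = exp(-Lambda(t | x))` and
#' `lambda(t | x) = Lambda(t | x) * d eta / d log t / t`. The excess hazard
#' may be negative if the fitted log cumulative hazard is locally
#' decreasing; such points are real features of the fit, not errors.
#'
#' @param object An `fpm_fit`.
#' @param newdata Data frame with `age_at_dx` and `sex` (ignored for a
#'   baseline-only fit, in which case one implicit row is used).
#' @param times Positive evaluation times (years since diagnosis).
#' @param type One of "survival", "hazard", "cumhaz".
#' @param ... Unused.
#' @return Tibble with columns `.row` (row of `newdata`), `time`, `estimate`.
#' @export
predict.fpm_fit <- function(object, newdata = NULL, times,
                            type = c("survival", "hazard", "cumhaz"), ...) {
  type <- match.arg(type)
  if (any(times <= 0)) abort("times must be positive")
  if (is.null(newdata)) {
    if (length(object$fit_info$covariates) > 0) {
      abort("newdata required for a model with covariates")
    }
    newdata <- tibble(.dummy = 1)
  }
  n_x <- nrow(newdata)
  Z <- fpm_covariates(object$fit_info,
                      newdata$age_at_dx %||% rep(0, n_x),
                      newdata$sex %||% rep("female", n_x))
  purrr::map_dfr(seq_along(times), function(j) {
    des <- fpm_design(object$fit_info, rep(times[j], n_x), Z)
    eta <- drop(des$X %*% object$coef)
    L <- exp(eta)
    est <- switch(type,
                  survival = exp(-L),
                  cumhaz = L,
                  hazard = L * drop(des$D %*% object$coef) / times[j])
    tibble(.row = seq_len(n_x), time = times[j], estimate = est)
  }) %>% arrange(.data$.row, .data$time)
}

#' @export
tidy.fpm_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = sqrt(diag(x$vcov)))
}

#' @export
glance.fpm_fit <- function(x, ...) {
  tibble(stage = x$stage, n = x$n, n_events = x$n_events,
         logLik = x$loglik, converged = x$converged,
         gradient_norm = x$gradient_norm,
         events_on_floor = x$events_on_floor)
}

#' @export
print.fpm_fit <- function(x, ...) {
  cat("Flexible parametric excess-hazard model",
      if (!is.na(x$stage)) paste0("(stage: ", x$stage, ")"), "\n")
  cat(sprintf("  n = %d, events = %d, logLik = %.3f, converged: %s\n",
              x$n, x$n_events, x$loglik, x$converged))
  invisible(x)
}

#' Serialise a fitted excess-hazard model to JSON (and back)
#'
#' Stores knots, centring constants, coefficients, covariance and
#' configuration so predictions are reproducible without refitting.
#'
#' @param fit An `fpm_fit`.
#' @param path Output path.
#' @return `fpm_write_json()` returns `path` invisibly; `fpm_read_json()`
#'   returns an `fpm_fit` usable with [predict.fpm_fit()].
#' @export
fpm_write_json <- function(fit, path) {
  payload <- unclass(fit)
  payload$cfg <- unclass(payload$cfg)
  payload$vcov <- unclass(payload$vcov)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname fpm_write_json
#' @export
fpm_read_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coef <- setNames(as.numeric(x$coef), names(x$coef))
  x$vcov <- as.matrix(x$vcov)
  x$fit_info <- lapply(setNames(nm = names(x$fit_info)), function(nm) {
    el <- x$fit_info[[nm]]
    if (startsWith(nm, "orth_")) as.matrix(el)
    else if (is.list(el)) unlist(el)
    else el
  })
  structure(x, class = "fpm_fit")
}
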