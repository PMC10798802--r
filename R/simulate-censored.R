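#' Baseline hazard of the scaled Beta(8, 1) failure-time law
#'
#' `lambda0(t) = f0(t / tau) / (1 - F0(t / tau))` with `f0`, `F0` the density
#' and distribution function of Beta(8, 1), i.e.
#' `lambda0(t) = 8 (t/tau)^7 / (1 - (t/tau)^8)`. Strictly increasing on
#' `(0, tau)` and divergent at the horizon, which keeps essentially all
#' failure times inside `[0, tau]`.
#'
#' @param t times in `[0, tau)`.
#' @param tau horizon (default 100).
#' @return Hazard values.
#' @export
baseline_hazard <- function(t, tau = 100) {
  if (any(t < 0) || any(t >= tau)) {
    abort("`t` must be in [0, tau); the hazard diverges at tau.")
  }
  u <- t / tau
  8 * u^7 / (1 - u^8)
}

#' Simulation configuration for censored data with time-varying covariates
#'
#' @param n sample size.
#' @param setup `"ph"` (proportional hazards, ~20% censoring) or `"nonph"`
#'   (quadratic + interaction log relative hazard, ~50% censoring).
#' @param tau time horizon.
#' @param delta_s fine-grid step used to integrate the cumulative hazard.
#' @param censor_rate_target target censoring fraction; defaults to 0.20
#'   (`ph`) / 0.50 (`nonph`).
#' @param censor_rate exponential censoring rate; when `NULL` it is calibrated
#'   to the target by [calibrate_censoring_rate()].
#' @param seed integer seed.
#' @export
censored_sim_config <- function(n, setup = c("ph", "nonph"), tau = 100,
                                delta_s = 0.01, censor_rate_target = NULL,
                                censor_rate = NULL, seed = 1) {
  setup <- match.arg(setup)
  if (is.null(censor_rate_target)) {
    censor_rate_target <- if (setup == "ph") 0.20 else 0.50
  }
  stopifnot(n >= 1, tau > 0, delta_s > 0, delta_s < tau,
            censor_rate_target > 0, censor_rate_target < 1)
  structure(
    list(n = as.integer(n), setup = setup, tau = tau, delta_s = delta_s,
         censor_rate_target = censor_rate_target, censor_rate = censor_rate,
         seed = as.integer(seed)),
    class = "censored_sim_config"
  )
}

#' Draw the subject-level covariate processes
#'
#' Per subject: `alpha_1..alpha_5 ~ U(0,1)` drive the two-harmonic Fourier
#' path `x1(t) = a1 + a2 sin(2 pi t / tau) + a3 cos(2 pi t / tau) +
#' a4 sin(4 pi t / tau) + a5 cos(4 pi t / tau)`; `q ~ U(0, tau)` places the
#' 0-to-1 jump of the step covariate `x2(t) = 1(t > q)` (left-continuous:
#' `x2(q) = 0`); static covariates `x3 ~ Bernoulli(0.6)`,
#' `x4 ~ Poisson(2)` truncated at 5 (rejection resampling), `x5 ~ Beta(2, 5)`.
#'
#' @param n number of subjects.
#' @param tau horizon.
#' @param seed integer seed.
#' @return Tibble with one row per subject: `id`, `alpha1..alpha5`, `q`,
#'   `x3`, `x4`, `x5`.
#' @export
gen_covariate_paths <- function(n, tau = 100, seed = 1) {
  set.seed(seed %% .Machine$integer.max)
  tibble(
    id = seq_len(n),
    alpha1 = runif(n), alpha2 = runif(n), alpha3 = runif(n),
    alpha4 = runif(n), alpha5 = runif(n),
    q = runif(n, 0, tau),
    x3 = rbinom(n, 1, 0.6),
    x4 = rtrunc_pois(n, 2, 5),
    x5 = rbeta(n, 2, 5)
  )
}

# Truncated Poisson by rejection: resample until <= upper (true truncation,
# not capping).
rtrunc_pois <- function(n, lambda, upper) {
  x <- rpois(n, lambda)
  while (any(bad <- x > upper)) x[bad] <- rpois(sum(bad), lambda)
  x
}

rtrunc_norm <- function(n, mean, sd, bound) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- abs(x) > bound)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Evaluate the time-varying covariates of simulated subjects
#'
#' @param subjects rows from [gen_covariate_paths()].
#' @param t times (recycled against subjects when one of the two has length
#'   one).
#' @param tau horizon.
#' @return Tibble with columns `x1`, `x2`.
#' @export
eval_sim_covariates <- function(subjects, t, tau = 100) {
  tibble(
    x1 = with(subjects, alpha1 + alpha2 * sin(2 * pi * t / tau) +
      alpha3 * cos(2 * pi * t / tau) + alpha4 * sin(4 * pi * t / tau) +
      alpha5 * cos(4 * pi * t / tau)),
    x2 = as.numeric(t > subjects$q)
  )
}

#' True conditional hazard of the censored simulation designs
#'
#' Setup `"ph"`: `lambda0(t) exp(2 x1(t) + 2 x2(t) + 2 x3 + 2 x4 + 2 x5)`
#' (proportional hazards in the static covariates). Setup `"nonph"`:
#' `lambda0(t) exp(2 x1(t)^2 + 2 x2(t) + 2 x3 x4 + 2 x5)` -- the squared
#' Fourier term and the `x3 x4` interaction break the Cox specification.
#'
#' @param t time.
#' @param x1,x2,x3,x4,x5 covariate values at `t`.
#' @param setup `"ph"` or `"nonph"`.
#' @param tau horizon.
#' @export
conditional_hazard <- function(t, x1, x2, x3, x4, x5,
                               setup = c("ph", "nonph"), tau = 100) {
  setup <- match.arg(setup)
  lp <- if (setup == "ph") {
    2 * x1 + 2 * x2 + 2 * x3 + 2 * x4 + 2 * x5
  } else {
    2 * x1^2 + 2 * x2 + 2 * x3 * x4 + 2 * x5
  }
  baseline_hazard(t, tau) * exp(lp)
}

# Hazard paths on the fine grid for a block of subjects: matrix with one row
# per subject, one column per grid point s in {0, delta_s, ..., tau - delta_s}.
hazard_matrix <- function(subjects, setup, tau, delta_s) {
  s <- seq(0, tau - delta_s, by = delta_s)
  lam0 <- baseline_hazard(s, tau)
  sin1 <- sin(2 * pi * s / tau); cos1 <- cos(2 * pi * s / tau)
  sin2 <- sin(4 * pi * s / tau); cos2 <- cos(4 * pi * s / tau)
  X1 <- subjects$alpha1 +
    outer(subjects$alpha2, sin1) + outer(subjects$alpha3, cos1) +
    outer(subjects$alpha4, sin2) + outer(subjects$alpha5, cos2)
  X2 <- outer(subjects$q, s, function(q, t) as.numeric(t > q))
  lp <- if (setup == "ph") {
    2 * X1 + 2 * X2 + 2 * (subjects$x3 + subjects$x4 + subjects$x5)
  } else {
    2 * X1^2 + 2 * X2 + 2 * (subjects$x3 * subjects$x4 + subjects$x5)
  }
  sweep(exp(lp), 2, lam0, "*")
}

#' Draw failure times by inverting the simulated survival functions
#'
#' The cumulative hazard is the Riemann sum
#' `Lambda(t) = delta_s * sum_{s <= t} lambda(s)` over the fine grid, the
#' survival function `S = exp(-Lambda)`, and the failure time
#' `T = sup{ t : S(t) >= u }` with `u ~ U(0, 1)`. Subjects whose survival at
#' `tau - delta_s` still exceeds `u` get `T = tau` (administrative cap; they
#' are treated as censored at the horizon downstream).
#'
#' @param lambda hazard matrix: one row per subject, one column per fine-grid
#'   point `s = 0, delta_s, ..., tau - delta_s`.
#' @param u uniform draws, one per subject.
#' @param tau,delta_s horizon and grid step.
#' @return Numeric vector of failure times (multiples of `delta_s`, or `tau`).
#' @export
draw_failure_times <- function(lambda, u, tau = 100, delta_s = 0.01) {
  s <- seq(0, tau - delta_s, by = delta_s)
  if (ncol(lambda) != length(s)) {
    abort("`lambda` must have one column per fine-grid point.")
  }
  cum <- delta_s * t(apply(lambda, 1, cumsum))
  thresh <- -log(u)
  count <- rowSums(cum <= thresh)  # S(t) >= u  <=>  Lambda(t) <= -log(u)
  ifelse(count >= length(s), tau, s[pmax(count, 1L)])
}

#' Apply exponential censoring
#'
#' `C ~ Exponential(rate)`, `y = min(T, C)`, `delta = 1(T <= C)`; failures
#' administratively capped at the horizon count as censored there.
#'
#' @param failure_times failure times (with `tau` marking capped subjects).
#' @param rate exponential censoring rate.
#' @param tau horizon.
#' @param cens optional pre-drawn censoring times (used by the calibration
#'   pilot); defaults to fresh exponential draws.
#' @return Tibble `y`, `delta`.
#' @export
apply_censoring <- function(failure_times, rate, tau = 100, cens = NULL) {
  if (is.null(cens)) cens <- rexp(length(failure_times), rate)
  y <- pmin(failure_times, cens)
  delta <- as.numeric(failure_times <= cens & failure_times < tau)
  tibble(y = y, delta = delta)
}

#' Calibrate the exponential censoring rate to a target censoring fraction
#'
#' Draws a Monte-Carlo pilot of failure times from the requested setup and
#' bisects on the exponential rate until the pilot censoring fraction is
#' within `tol` of the target.
#'
#' @param setup `"ph"` or `"nonph"`.
#' @param target desired censoring fraction in (0, 1).
#' @param seed integer seed for the pilot.
#' @param m pilot size.
#' @param tol calibration tolerance on the censoring fraction.
#' @param tau,delta_s horizon and fine-grid step.
#' @return The calibrated rate (pilot censoring fraction in attribute
#'   `"achieved"`).
#' @export
calibrate_censoring_rate <- function(setup = c("ph", "nonph"), target = NULL,
                                     seed = 1, m = 20000, tol = 0.01,
                                     tau = 100, delta_s = 0.01) {
  setup <- match.arg(setup)
  if (is.null(target)) target <- if (setup == "ph") 0.20 else 0.50
  stopifnot(target > 0, target < 1)
  ft <- pilot_failure_times(setup, m, seed, tau, delta_s)
  set.seed((seed + 1L) %% .Machine$integer.max)
  e <- rexp(m, 1)  # censoring C = e / rate, fixed across bisection steps

  cens_frac <- function(rate) 1 - mean(ft <= e / rate & ft < tau)
  lo <- 1e-8; hi <- 1
  while (cens_frac(hi) < target && hi < 1e6) hi <- hi * 4
  if (cens_frac(hi) < target || cens_frac(lo) > target) {
    abort("bisection bracket does not contain the target censoring rate.")
  }
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    if (cens_frac(mid) < target) lo <- mid else hi <- mid
    if (abs(cens_frac(mid) - target) < tol / 4) break
  }
  rate <- sqrt(lo * hi)
  structure(rate, achieved = cens_frac(rate))
}

pilot_failure_times <- function(setup, m, seed, tau, delta_s,
                                chunk = 250L) {
  subjects <- gen_covariate_paths(m, tau, seed)
  u <- runif(m)
  out <- numeric(m)
  for (s0 in seq(1, m, by = chunk)) {
    rows <- s0:min(s0 + chunk - 1L, m)
    out[rows] <- draw_failure_times(
      hazard_matrix(subjects[rows, ], setup, tau, delta_s), u[rows],
      tau, delta_s
    )
  }
  out
}

#' Simulate a censored data set with time-varying covariates
#'
#' Runs the full pipeline: covariate processes, fine-grid survival inversion,
#' exponential censoring (calibrated to the setup's target rate unless a rate
#' is given), and assembly into the long-format counting-process layout whose
#' intervals are partitioned by the pooled observed times (each subject has
#' one row per grid point `t_j <= y_i` carrying the covariates in force at
#' `t_j`).
#'
#' @param config a [censored_sim_config()].
#' @return Long-format tibble (`id`, `tstart`, `tstop`, `event`,
#'   `x1..x5`) with attributes `subjects` (the latent path parameters),
#'   `censor_rate` and `censor_frac`.
#' @export
sim_censored <- function(config) {
  stopifnot(inherits(config, "censored_sim_config"))
  n <- config$n; tau <- config$tau; delta_s <- config$delta_s
  ft <- pilot_failure_times(config$setup, n, config$seed, tau, delta_s)
  subjects <- gen_covariate_paths(n, tau, config$seed)

  rate <- config$censor_rate %||% calibrate_censoring_rate(
    config$setup, config$censor_rate_target,
    seed = (config$seed + 977L) %% .Machine$integer.max,
    tau = tau, delta_s = delta_s
  )
  set.seed((config$seed + 2L) %% .Machine$integer.max)
  yd <- apply_censoring(ft, as.numeric(rate), tau)

  grid <- build_time_grid(yd$y, "censored")
  pts <- grid$points
  counts <- findInterval(yd$y + 1e-12, pts)
  i_idx <- rep(seq_len(n), counts)
  tj <- pts[sequence(counts)]
  # covariates in force at t_j: the fine-grid step path holds the value of
  # the right endpoint of each (s - delta_s, s] micro-interval
  tj_snap <- pmin(ceiling(tj / delta_s - 1e-9) * delta_s, tau - delta_s)
  xv <- eval_sim_covariates(subjects[i_idx, ], tj_snap, tau)
  long <- tibble(
    id = i_idx,
    tstart = c(0, pts)[sequence(counts)],
    tstop = tj,
    event = as.numeric(yd$delta[i_idx] * (abs(tj - yd$y[i_idx]) < 1e-12)),
    x1 = xv$x1, x2 = xv$x2,
    x3 = subjects$x3[i_idx], x4 = subjects$x4[i_idx],
    x5 = subjects$x5[i_idx]
  )
  attr(long, "subjects") <- dplyr::bind_cols(subjects, yd)
  attr(long, "censor_rate") <- as.numeric(rate)
  attr(long, "censor_frac") <- 1 - mean(yd$delta)
  long
}

#' True conditional survival curve of a simulated subject
#'
#' @param subject one row of the `subjects` attribute of [sim_censored()]
#'   (or of [gen_covariate_paths()]).
#' @param times times at which to return `S(t | path)`.
#' @param setup,tau,delta_s as in the generator.
#' @return Tibble `time`, `surv`.
#' @export
true_survival_censored <- function(subject, times, setup = c("ph", "nonph"),
                                   tau = 100, delta_s = 0.01) {
  setup <- match.arg(setup)
  lam <- hazard_matrix(subject, setup, tau, delta_s)
  cum <- delta_s * cumsum(lam[1, ])
  s <- seq(0, tau - delta_s, by = delta_s)
  idx <- pmax(findInterval(times, s), 1L)
  tibble(time = times, surv = exp(-cum[idx]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
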