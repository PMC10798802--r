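#' Step-function conditional distribution estimates
#'
#' A `cond_cdf` holds the estimated conditional distribution function on the
#' training grid: times `t_1 < ... < t_m` and values `F(t_j | x)`. In censored
#' mode it is built as `1 - S` from the cumulative-hazard Riemann sum; in
#' uncensored mode it carries the fixed `1/n` mass at `t_1`. Values between
#' grid points follow the step-function convention (evaluate at the largest
#' grid point `<= y`), and the estimate is held constant beyond the last grid
#' point: the discretised cumulative hazard has support only on observed times.
#'
#' @name cond_cdf
NULL

new_cond_cdf <- function(time, cdf, mode, n_train = NA_integer_) {
  structure(
    list(time = as.numeric(time), cdf = as.numeric(cdf), mode = mode,
         n_train = n_train),
    class = "cond_cdf"
  )
}

#' Reconstruct a conditional survival curve from a log-hazard estimate
#'
#' Plugs an estimated log conditional hazard into the survival identity
#' `S(t | x) = exp(-\sum_{t_j <= t} e^{h(t_{j-1}, t_j, x(t_j))} (t_j - t_{j-1}))`.
#' For any finite `h` the result is a valid survival function: non-increasing
#' and in (0, 1].
#'
#' @param h a fitted [hazard_fit] or a function `f(tprev, tcur, X)` returning
#'   one log-hazard value per row of the covariate matrix `X`.
#' @param path a [covariate_path()] covering `[0, max(grid points)]`.
#' @param grid a censored-mode [build_time_grid()]; taken from `h` when it is
#'   a fitted model.
#' @param clamp numeric bounds applied to `h` inside `exp()`.
#' @return A [cond_cdf] (use `$cdf` / `surv_values()` for `F` and `S`).
#' @export
survival_curve <- function(h, path, grid = NULL, clamp = c(-30, 30)) {
  grid <- resolve_grid(h, grid, "censored")
  pts <- grid$points
  X <- eval_path(path, pts)
  hv <- eval_h(h, c(0, pts[-length(pts)]), pts, X)
  cum <- cumsum(exp(pmin(pmax(hv, clamp[1]), clamp[2])) * grid_widths(grid))
  surv <- pmax(exp(-cum), 1e-15)
  new_cond_cdf(pts, 1 - surv, "censored")
}

#' Reconstruct a conditional distribution function from a log-hazard estimate
#'
#' Applies the uncensored-mode identity
#' `F(y | x) = I(t_1 <= y) (1 - (n-1)/n * exp(-\sum_{j >= 2, t_j <= y}
#' e^{h(t_{j-1}, t_j, x)} (t_j - t_{j-1})))`, which places mass `1/n` at the
#' smallest training response and is non-decreasing and bounded in `[0, 1)`
#' for any finite `h`.
#'
#' @param x a single covariate vector (named or in training column order).
#' @param n_train the training-sample size `n` in the `1/n` mass; taken from
#'   `h` when it is a fitted model.
#' @inheritParams survival_curve
#' @return A [cond_cdf] with `F(t_1) = 1/n` exactly.
#' @export
cdf_curve <- function(h, x, grid = NULL, n_train = NULL, clamp = c(-30, 30)) {
  grid <- resolve_grid(h, grid, "uncensored")
  if (is.null(n_train) && inherits(h, "hazard_fit")) n_train <- h$n_train
  if (is.null(n_train) || n_train < 2) abort("`n_train` must be >= 2.")
  pts <- grid$points
  m <- length(pts)
  Fhat <- rep(1 / n_train, m)
  if (m > 1) {
    X <- matrix(rep(as.numeric(x), each = m - 1), nrow = m - 1)
    colnames(X) <- names(x)
    hv <- eval_h(h, pts[-m], pts[-1], X)
    cum <- cumsum(exp(pmin(pmax(hv, clamp[1]), clamp[2])) * diff(pts))
    Fhat[-1] <- 1 - (1 - 1 / n_train) * pmax(exp(-cum), 1e-15)
  }
  new_cond_cdf(pts, Fhat, "uncensored", as.integer(n_train))
}

resolve_grid <- function(h, grid, mode) {
  if (is.null(grid) && inherits(h, "hazard_fit")) grid <- h$grid
  if (is.null(grid) || !inherits(grid, "time_grid") || grid$mode != mode) {
    abort(sprintf("a %s-mode `grid` is required.", mode))
  }
  grid
}

# Dispatch log-hazard evaluation: plain functions for tests and oracles,
# fitted networks for the real thing.
eval_h <- function(h, tprev, tcur, X) {
  if (inherits(h, "hazard_fit")) {
    predict_h(h, tprev, tcur, X)
  } else if (is.function(h)) {
    as.numeric(h(tprev, tcur, X))
  } else {
    abort("`h` must be a hazard_fit or a function(tprev, tcur, X).")
  }
}

#' Evaluate a step CDF at arbitrary points
#'
#' @param cdf a [cond_cdf].
#' @param y numeric vector.
#' @return `F` at the largest grid point `<= y` (0 below the first grid
#'   point, constant above the last).
#' @export
eval_cdf <- function(cdf, y) {
  stopifnot(inherits(cdf, "cond_cdf"))
  idx <- findInterval(y + 1e-12, cdf$time)
  c(0, cdf$cdf)[idx + 1L]
}

#' Survival values of a conditional CDF
#'
#' @param cdf a [cond_cdf].
#' @return `1 - F` on the grid.
#' @export
surv_values <- function(cdf) {
  stopifnot(inherits(cdf, "cond_cdf"))
  1 - cdf$cdf
}

#' Conditional mean implied by an estimated distribution function
#'
#' The Riemann--Stieltjes sum over grid jumps,
#' `\sum_j t_j (F(t_j) - F(t_{j-1}))` with `F(t_0) = 0`.
#'
#' @param cdf a [cond_cdf].
#' @return A single number.
#' @export
conditional_mean <- function(cdf) {
  stopifnot(inherits(cdf, "cond_cdf"))
  sum(cdf$time * diff(c(0, cdf$cdf)))
}

#' Quantiles of a step CDF (left-continuous generalised inverse)
#'
#' `Q(p) = min { t_j : F(t_j) >= p }`; when no grid value reaches `p` (the
#' uncensored estimate is bounded below 1) the last grid point is returned.
#'
#' @param x a [cond_cdf].
#' @param probs probabilities in (0, 1).
#' @param ... unused.
#' @export
quantile.cond_cdf <- function(x, probs, ...) {
  if (any(probs <= 0 | probs >= 1)) abort("`probs` must be in (0, 1).")
  m <- length(x$time)
  purrr::map_dbl(probs, function(p) {
    j <- which(x$cdf >= p - 1e-12)
    if (length(j) == 0) x$time[m] else x$time[j[1]]
  })
}

#' Equal-tailed predictive interval from an estimated conditional CDF
#'
#' @param cdf a [cond_cdf].
#' @param level coverage level in (0, 1); the interval is
#'   `[Q((1-level)/2), Q((1+level)/2)]`.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
predictive_interval <- function(cdf, level = 0.9) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single number in (0, 1).")
  }
  q <- quantile(cdf, c((1 - level) / 2, (1 + level) / 2))
  c(lower = q[1], upper = q[2])
}

#' @export
print.cond_cdf <- function(x, ...) {
  cat(sprintf(
    "<cond_cdf> (%s mode) %d grid points on [%g, %g], F range [%.4g, %.4g]\n",
    x$mode, length(x$time), min(x$time), max(x$time), min(x$cdf), max(x$cdf)
  ))
  invisible(x)
}

#' @export
tidy.cond_cdf <- function(x, ...) {
  tibble(time = x$time, cdf = x$cdf, surv = 1 - x$cdf)
}

#' @export
autoplot.cond_cdf <- function(object, what = c("cdf", "surv"), ...) {
  what <- match.arg(what)
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data[[what]])) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = if (object$mode == "censored") "time" else "response",
      y = if (what == "cdf") "estimated F(y | x)" else "estimated S(t | x)"
    )
}
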