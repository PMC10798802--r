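#' Simulate uncensored regression data with mixture errors
#'
#' Draws i.i.d. data from
#' `y = x1^2 + x2 x3 + x3 x4 + x5 + eps * g(x)` with
#' `x1 ~ N(0,1)` truncated at +/-3 (rejection), `x2 ~ U(0,1)`,
#' `x3 ~ Beta(0.5, 0.5)`, `x4 ~ Bernoulli(0.5)`, `x5 ~ Poisson(2)` truncated
#' at 5, and `eps` a mixture of `N(-2,1)`, `N(0,1)` and `0.5 x6^2` with
#' probabilities (0.1, 0.7, 0.2). The latent `x6` builds the error and is
#' never exposed as a predictor.
#'
#' Setup `"indep"`: `x6 ~ N(1, 1)` independent of everything and `g(x) = c`
#' -- homoscedastic errors uncorrelated with the mean (here `E[eps] = 0`).
#' Setup `"corr"`: `x6 | x1 ~ N(1 + 0.5 x1, 0.75)` (variance 0.75) and
#' `g(x) = c x1^2` -- heteroscedastic errors correlated with the covariates,
#' the regime where an L2 mean fit plus residual shift breaks down.
#'
#' @param n sample size.
#' @param setup `"indep"` or `"corr"`.
#' @param c noise scale (0.5 or 1 in the reference experiments).
#' @param seed integer seed.
#' @return Tibble `y`, `x1..x5`.
#' @export
sim_uncensored <- function(n, setup = c("indep", "corr"), c = 0.5, seed = 1) {
  setup <- match.arg(setup)
  stopifnot(c > 0, n >= 1)
  set.seed(seed %% .Machine$integer.max)
  x1 <- rtrunc_norm(n, 0, 1, 3)
  x2 <- runif(n)
  x3 <- rbeta(n, 0.5, 0.5)
  x4 <- rbinom(n, 1, 0.5)
  x5 <- rtrunc_pois(n, 2, 5)
  x6 <- if (setup == "indep") rnorm(n, 1, 1) else rnorm(n, 1 + 0.5 * x1, sqrt(0.75))
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.1, 0.7, 0.2))
  eps <- dplyr::case_when(
    comp == 1 ~ rnorm(n, -2, 1),
    comp == 2 ~ rnorm(n, 0, 1),
    TRUE ~ 0.5 * x6^2
  )
  g <- if (setup == "indep") rep(c, n) else c * x1^2
  tibble(
    y = x1^2 + x2 * x3 + x3 * x4 + x5 + eps * g,
    x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5
  )
}

#' True conditional distribution function of the mixture-error designs
#'
#' For response value(s) `y` and covariates `x1..x5`,
#' `F(y | x) = P(eps <= z)` with `z = (y - m(x)) / g(x)` and
#' `m(x) = x1^2 + x2 x3 + x3 x4 + x5`. The mixture gives
#' `F = 0.1 Phi(z + 2) + 0.7 Phi(z) + 0.2 P(0.5 x6^2 <= z | x1)`, and the
#' third term is a plain normal interval probability,
#' `Phi((sqrt(2z) - mu)/sigma) - Phi((-sqrt(2z) - mu)/sigma)` for `z > 0`,
#' with `(mu, sigma) = (1, 1)` in setup `"indep"` and
#' `(1 + 0.5 x1, sqrt(0.75))` in setup `"corr"`. When `g(x) = 0` (possible in
#' setup `"corr"` at `x1 = 0`) the response is degenerate at `m(x)` and the
#' CDF is a step there.
#'
#' @param y response values.
#' @param data data frame with `x1..x5` (rows recycled against `y` when one
#'   of the two has length one).
#' @param setup,c as in [sim_uncensored()].
#' @return Vector of true conditional probabilities.
#' @export
true_cdf_uncensored <- function(y, data, setup = c("indep", "corr"), c = 0.5) {
  setup <- match.arg(setup)
  m <- data$x1^2 + data$x2 * data$x3 + data$x3 * data$x4 + data$x5
  g <- if (setup == "indep") rep(c, nrow(data)) else c * data$x1^2
  mu <- if (setup == "indep") rep(1, nrow(data)) else 1 + 0.5 * data$x1
  sig <- if (setup == "indep") 1 else sqrt(0.75)
  k <- max(length(y), length(m))
  y <- rep_len(y, k); m <- rep_len(m, k); g <- rep_len(g, k)
  mu <- rep_len(mu, k)
  out <- numeric(k)
  deg <- g <= 0
  out[deg] <- as.numeric(y[deg] >= m[deg])
  if (any(!deg)) {
    z <- (y[!deg] - m[!deg]) / g[!deg]
    r <- sqrt(2 * pmax(z, 0))
    p3 <- ifelse(z > 0,
      pnorm((r - mu[!deg]) / sig) - pnorm((-r - mu[!deg]) / sig), 0
    )
    out[!deg] <- 0.1 * pnorm(z + 2) + 0.7 * pnorm(z) + 0.2 * p3
  }
  out
}

#' True conditional mean of the mixture-error designs
#'
#' `E[Y | x] = m(x) + g(x) E[eps | x1]` with
#' `E[eps | x1] = -0.2 + 0.1 (mu^2 + sigma^2)`; zero in setup `"indep"`.
#'
#' @inheritParams true_cdf_uncensored
#' @export
true_mean_uncensored <- function(data, setup = c("indep", "corr"), c = 0.5) {
  setup <- match.arg(setup)
  m <- data$x1^2 + data$x2 * data$x3 + data$x3 * data$x4 + data$x5
  if (setup == "indep") {
    m  # E[eps] = 0.1(-2) + 0.2 * 0.5 * (1 + 1) = 0
  } else {
    mu <- 1 + 0.5 * data$x1
    m + (c * data$x1^2) * (-0.2 + 0.1 * (mu^2 + 0.75))
  }
}

#' Triangular distribution on `[-1, 1]`
#'
#' Density `1 - |x|`; used for both covariates and noise in the kernel
#' comparison designs.
#'
#' @param x,p,n quantile / probability / sample-size arguments.
#' @export
ptriangular <- function(x) {
  ifelse(x <= -1, 0, ifelse(x >= 1, 1,
    ifelse(x < 0, (1 + x)^2 / 2, 1 - (1 - x)^2 / 2)
  ))
}

#' @rdname ptriangular
#' @export
qtriangular <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.5, sqrt(2 * p) - 1, 1 - sqrt(2 * (1 - p)))
}

#' @rdname ptriangular
#' @export
rtriangular <- function(n) qtriangular(runif(n))

#' Simulate the sine-regression kernel-comparison designs
#'
#' 1-D: `y = 2 sin(3.1416 x) + eps` with `x` and `eps` triangular on
#' `[-1, 1]`. 2-D adds `x2 ~ U(-1, 1)` to the mean:
#' `y = 2 sin(3.1416 x1) + x2 + eps`.
#'
#' @param n sample size.
#' @param dims 1 or 2 covariates.
#' @param seed integer seed.
#' @return Tibble `y`, `x1` (and `x2` when `dims = 2`).
#' @export
sim_kernel_example <- function(n, dims = 1, seed = 1) {
  stopifnot(dims %in% c(1, 2))
  set.seed(seed %% .Machine$integer.max)
  x1 <- rtriangular(n)
  eps <- rtriangular(n)
  if (dims == 1) {
    tibble(y = 2 * sin(3.1416 * x1) + eps, x1 = x1)
  } else {
    x2 <- runif(n, -1, 1)
    tibble(y = 2 * sin(3.1416 * x1) + x2 + eps, x1 = x1, x2 = x2)
  }
}

#' True conditional CDF of the kernel-comparison designs
#'
#' The triangular noise CDF shifted by the mean function.
#'
#' @param y response values.
#' @param data data frame with `x1` (and `x2` for the 2-D design).
#' @export
true_cdf_kernel <- function(y, data) {
  m <- 2 * sin(3.1416 * data$x1)
  if ("x2" %in% names(data)) m <- m + data$x2
  ptriangular(y - m)
}

#' Evaluation grid for the kernel-comparison designs
#'
#' Regular grid with steps 0.067 in each covariate axis and 0.054 in the
#' response axis, spanning the covariate support `[-1, 1]` and the response
#' support (`[-3, 3]` in 1-D, `[-4, 4]` in 2-D).
#'
#' @param dims 1 or 2.
#' @return Tibble of grid points `x1` (, `x2`), `y`.
#' @export
kernel_eval_grid <- function(dims = 1) {
  stopifnot(dims %in% c(1, 2))
  xg <- seq(-1, 1, by = 0.067)
  if (dims == 1) {
    tidyr::expand_grid(x1 = xg, y = seq(-3, 3, by = 0.054))
  } else {
    tidyr::expand_grid(x1 = xg, x2 = xg, y = seq(-4, 4, by = 0.054))
  }
}
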