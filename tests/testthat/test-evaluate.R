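test_that("the censoring-time Kaplan-Meier matches hand-computed values", {
  # censorings at 2, 3, 5 with risk sets 5, 4, 2
  y <- 1:6
  delta <- c(1, 0, 0, 1, 0, 1)
  G <- km_censoring(y, delta)
  expect_equal(eval_G(G, c(1.5, 2, 2.5, 3, 4.9, 5, 6)),
               c(1, 0.8, 0.8, 0.6, 0.6, 0.3, 0.3))
  expect_equal(eval_G(G, c(2, 5), left = TRUE), c(1, 0.6))

  none <- km_censoring(c(1, 2, 3), c(1, 1, 1))
  expect_equal(eval_G(none, c(0.5, 3)), c(1, 1))
  all4 <- km_censoring(rep(1, 4), rep(0, 4))
  expect_equal(eval_G(all4, 1), 0)
})

test_that("the C-index hits 1 for perfect ordering and 0.5 for no signal", {
  y <- 1:4
  delta <- rep(1, 4)
  lam <- c(4, 3, 2, 1)
  S <- outer(y, lam, function(t, l) exp(-l * t))  # S[i, j] = S(y_i | x_j)
  expect_equal(c_index_td(S, y, delta), 1)
  expect_equal(c_index_td(matrix(0.7, 4, 4), y, delta), 0.5)
  expect_error(c_index_td(S[1, 1, drop = FALSE], y[1], 1), "comparable")
})

test_that("the C-index equals brute-force pair enumeration", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(8:30, 1)
    y <- sample(1:12, n, replace = TRUE)  # forces event-time ties
    delta <- rbinom(n, 1, 0.7)
    S <- matrix(runif(n * n), n)
    S[sample(n * n, 5)] <- 0.5  # force some prediction ties
    num <- 0; den <- 0
    for (i in 1:n) for (j in 1:n) {
      if (delta[i] == 1 && y[i] < y[j]) {
        den <- den + 1
        if (S[i, i] < S[i, j]) num <- num + 1
        if (S[i, i] == S[i, j]) num <- num + 0.5
      }
    }
    expect_equal(c_index_td(S, y, delta), num / den)
  }
})

test_that("Brier score and binomial log-likelihood match hand computation", {
  # no censoring, S = 1, t before all events -> 0
  y <- c(2, 3, 4); delta <- c(1, 1, 1)
  G <- km_censoring(y, delta)
  expect_equal(brier_score(1, rep(1, 3), y, delta, G), 0)
  # no censoring, S = 0.5, t after all events -> 0.25
  expect_equal(brier_score(5, rep(0.5, 3), y, delta, G), 0.25)

  # one censored subject, IPCW weights by hand
  y5 <- 1:5; d5 <- c(1, 0, 1, 1, 1)
  G5 <- km_censoring(y5, d5)  # censoring at 2 with 4 at risk -> G = 0.75
  s <- c(0.9, 0.8, 0.4, 0.6, 0.3)
  expect_equal(
    brier_score(3.5, s, y5, d5, G5),
    (0.9^2 / 1 + 0.4^2 / 0.75 + 0.4^2 / 0.75 + 0.7^2 / 0.75) / 5
  )
  expect_equal(
    binomial_ll(3.5, s, y5, d5, G5),
    (log(0.1) / 1 + log(0.6) / 0.75 + log(0.6) / 0.75 + log(0.3) / 0.75) / 5
  )
})

test_that("without censoring the Brier score is a plain squared error", {
  set.seed(4)
  y <- rexp(200); delta <- rep(1, 200)
  G <- km_censoring(y, delta)
  s <- runif(200)
  for (t in quantile(y, c(0.2, 0.5, 0.8))) {
    expect_equal(brier_score(t, s, y, delta, G),
                 mean((as.numeric(y > t) - s)^2))
  }
})

test_that("probability clipping keeps the log-likelihood finite", {
  y <- c(1, 2); delta <- c(1, 1)
  G <- km_censoring(y, delta)
  expect_warning(v <- binomial_ll(1.5, c(0, 1), y, delta, G), "clipped")
  expect_true(is.finite(v))
})

test_that("score integration is a time-averaged trapezoid rule", {
  expect_equal(integrate_scores(c(0, 2, 7), rep(3, 3)), 3)
  expect_equal(integrate_scores(c(0, 0.5, 1), c(0, 0.5, 1)), 0.5)
  expect_error(integrate_scores(c(1, 1), c(0, 0)), "degenerate")

  set.seed(8)
  times <- sort(runif(15))
  vals <- rnorm(15)
  f <- approxfun(times, vals)
  grid <- seq(min(times), max(times), length.out = 2e5)
  riemann <- mean(f(grid))
  expect_equal(integrate_scores(times, vals), riemann, tolerance = 1e-3)
})

test_that("MADE filters on the true CDF and averages absolute deviations", {
  f_true <- c(0.0005, 0.2, 0.5, 0.9995, 0.7)
  expect_equal(made(f_true, f_true), 0)
  expect_equal(made(f_true + 0.1, f_true), 0.1)
  set.seed(2)
  fh <- runif(50); ft <- runif(50)
  keep <- ft >= 0.001 & ft <= 0.999
  expect_equal(made(fh, ft), mean(abs(fh - ft)[keep]))
  expect_error(made(1, 0.99999), "no evaluation point")
})

test_that("prediction errors and coverage behave on toy data", {
  expect_equal(prediction_errors(1:5, 1:5)$mean_sq, 0)
  e <- prediction_errors(c(1, 2, 4, 9, 0), c(0, 2, 2, 4, 1))
  expect_equal(e$mean_sq, mean(c(1, 0, 4, 25, 1)))
  expect_equal(e$median_sq, 1)
  iv <- tibble::tibble(lower = rep(-Inf, 3), upper = rep(Inf, 3))
  expect_equal(coverage_rate(iv, rnorm(3)), 1)
  iv2 <- tibble::tibble(lower = c(0, 0), upper = c(1, 1))
  expect_equal(coverage_rate(iv2, c(0.5, 2)), 0.5)
})

test_that("percentile calibration recovers targets under the true CDF", {
  set.seed(19)
  n <- 2000
  mu <- rnorm(n, sd = 2)
  y <- rnorm(n, mu)
  grid <- seq(-12, 12, by = 0.01)
  cdfs <- lapply(mu, function(m) {
    condhaz:::new_cond_cdf(grid, pnorm(grid, m), "uncensored", n)
  })
  cal <- percentile_calibration(cdfs, y, c(0.1, 0.5, 0.9))
  for (k in 1:3) {
    p <- cal$target[k]
    expect_lt(abs(cal$empirical[k] - p), 3 * sqrt(p * (1 - p) / n) + 0.01)
  }
  # degenerate CDFs below all responses never cover
  low <- condhaz:::new_cond_cdf(-100, 1, "uncensored", n)
  cal0 <- percentile_calibration(rep(list(low), 5), rep(0, 5), 0.5)
  expect_equal(cal0$empirical, 0)
})

test_that("cross-validation averages per-fold panels", {
  d <- sim_censored(censored_sim_config(40, "ph", censor_rate = 0.011, seed = 9))
  cfg <- training_config(seed = 2, max_epochs = 5, batch_size = 50)
  # small folds can drop zero-weight terms near the fold maximum; that
  # warning is part of the contract and not under test here
  res <- suppressWarnings(cross_validate(d, k = 4, config = cfg, n_times = 20))
  expect_equal(nrow(res), 4)
  s <- attr(res, "summary")
  expect_equal(s$ibs, mean(res$ibs, na.rm = TRUE))
  expect_true(all(res$c_index >= 0 & res$c_index <= 1, na.rm = TRUE))
})
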