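const_path <- function(upto = 10) covariate_path(upto, matrix(1))

test_that("survival reconstruction matches the constant-hazard closed form", {
  lam <- 0.7
  h <- function(tp, tc, X) rep(log(lam), nrow(X))
  g <- build_time_grid(c(1, 2), "censored")
  sc <- survival_curve(h, const_path(2), g)
  expect_equal(surv_values(sc), exp(-lam * c(1, 2)))
  # before the first grid point nothing has accumulated
  expect_equal(1 - eval_cdf(sc, 0.5), 1)
})

test_that("reconstructed survival is valid for arbitrary h", {
  g <- build_time_grid(sort(runif(40, 0, 5)), "censored")
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(1, sd = 10)
    h <- function(tp, tc, X) sin(3 * tc) * 5 + a
    sc <- survival_curve(h, const_path(5), g)
    s <- surv_values(sc)
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(diff(s) <= 0))
  }
})

test_that("cdf reconstruction matches direct substitution", {
  h0 <- function(tp, tc, X) rep(0, nrow(X))
  g <- build_time_grid(c(0, 1), "uncensored")
  cdf <- cdf_curve(h0, x = 1, grid = g, n_train = 2)
  expect_equal(cdf$cdf[1], 0.5)  # 1/n exactly
  expect_equal(cdf$cdf[2], 1 - 0.5 * exp(-1))
  expect_equal(eval_cdf(cdf, -1), 0)  # indicator I(t1 <= y)
  expect_equal(eval_cdf(cdf, 10), cdf$cdf[2])  # constant beyond the grid
})

test_that("cdf reconstruction equals a cumulative-sum loop oracle", {
  set.seed(42)
  pts <- sort(rnorm(40))
  g <- build_time_grid(pts, "uncensored")
  b <- rnorm(1)
  h <- function(tp, tc, X) 0.3 * tc - 0.1 * tp + b
  cdf <- cdf_curve(h, x = 2, grid = g, n_train = 40)
  expected <- numeric(40)
  expected[1] <- 1 / 40
  acc <- 0
  for (j in 2:40) {
    acc <- acc + exp(h(pts[j - 1], pts[j], matrix(2))) * (pts[j] - pts[j - 1])
    expected[j] <- 1 - (1 - 1 / 40) * exp(-acc)
  }
  expect_equal(cdf$cdf, expected, tolerance = 1e-12)
  expect_true(all(diff(cdf$cdf) >= 0))
  expect_true(all(cdf$cdf >= 0 & cdf$cdf < 1))
})

test_that("conditional means are Riemann-Stieltjes sums over the jumps", {
  two <- condhaz:::new_cond_cdf(c(1, 3), c(0.5, 1), "uncensored", 2)
  expect_equal(conditional_mean(two), 2)
  degen <- condhaz:::new_cond_cdf(5, 1, "uncensored", 10)
  expect_equal(conditional_mean(degen), 5)

  set.seed(9)
  t <- sort(rnorm(20))
  jumps <- runif(20)
  jumps <- jumps / sum(jumps)
  cdf <- condhaz:::new_cond_cdf(t, cumsum(jumps), "uncensored", 20)
  expect_equal(conditional_mean(cdf), sum(t * jumps))
})

test_that("conditional mean of an empirical CDF is the sample mean exactly", {
  set.seed(13)
  y <- rnorm(50)
  t <- sort(y)
  cdf <- condhaz:::new_cond_cdf(t, seq_along(t) / 50, "uncensored", 50)
  expect_equal(conditional_mean(cdf), mean(y))
})

test_that("predictive intervals are equal-tailed generalised-inverse quantiles", {
  unif <- condhaz:::new_cond_cdf(1:100, (1:100) / 100, "uncensored", 100)
  expect_equal(unname(predictive_interval(unif, 0.90)), c(5, 95))
  degen <- condhaz:::new_cond_cdf(5, 1, "uncensored", 2)
  expect_equal(unname(predictive_interval(degen, 0.5)), c(5, 5))
  expect_error(predictive_interval(unif, 1.2), "in \\(0, 1\\)")
  expect_error(quantile(unif, 0), "in \\(0, 1\\)")

  # captured mass between the endpoints is at least the nominal level
  set.seed(3)
  for (k in 1:5) {
    jumps <- runif(30); jumps <- jumps / sum(jumps)
    cdf <- condhaz:::new_cond_cdf(sort(rnorm(30)), cumsum(jumps),
                                  "uncensored", 30)
    iv <- predictive_interval(cdf, 0.9)
    f_hi <- eval_cdf(cdf, iv[["upper"]])
    f_lo_minus <- max(0, c(0, cdf$cdf)[findInterval(iv[["lower"]], cdf$time)])
    expect_gte(f_hi - f_lo_minus, 0.9 - 1e-10)
  }
})

test_that("tidy and autoplot expose the step function", {
  cdf <- condhaz:::new_cond_cdf(1:3, c(0.2, 0.5, 0.9), "uncensored", 5)
  td <- tidy(cdf)
  expect_equal(td$surv, 1 - td$cdf)
  expect_s3_class(autoplot(cdf), "ggplot")
})
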