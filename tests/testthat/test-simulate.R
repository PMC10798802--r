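test_that("the scaled-Beta baseline hazard follows its closed form", {
  expect_equal(baseline_hazard(0), 0)
  expect_equal(baseline_hazard(50, tau = 100), 8 * 0.5^7 / (1 - 0.5^8))
  t <- seq(0.5, 99.5, by = 0.5)
  expect_true(all(diff(baseline_hazard(t)) > 0))
  expect_error(baseline_hazard(100), "diverges")
  expect_error(baseline_hazard(-1), "\\[0, tau\\)")
})

test_that("simulated covariate processes have the stated construction", {
  subj <- gen_covariate_paths(10000, seed = 17)
  # Fourier path at 0: sines vanish, cosines are 1
  x0 <- eval_sim_covariates(subj, 0)
  expect_equal(x0$x1, subj$alpha1 + subj$alpha3 + subj$alpha5)
  # step covariate is left-continuous at its jump
  x_at_q <- eval_sim_covariates(subj, subj$q)
  expect_true(all(x_at_q$x2 == 0))
  x_after <- eval_sim_covariates(subj, subj$q + 1e-9)
  expect_true(all(x_after$x2 == 1))
  # moments and supports
  expect_lt(abs(mean(subj$x3) - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))
  expect_true(all(subj$x4 %in% 0:5))
  expect_true(all(subj$x5 > 0 & subj$x5 < 1))
})

test_that("conditional hazards implement both setups", {
  t <- 30
  lam0 <- baseline_hazard(t)
  expect_equal(conditional_hazard(t, 0, 0, 0, 0, 0, "ph"), lam0)
  expect_equal(conditional_hazard(t, 0, 0, 0, 0, 0, "nonph"), lam0)
  # proportional hazards: x3 = 1 vs 0 multiplies the hazard by e^2
  expect_equal(
    conditional_hazard(t, 0.2, 1, 1, 2, 0.3, "ph") /
      conditional_hazard(t, 0.2, 1, 0, 2, 0.3, "ph"),
    exp(2)
  )
  # the squared x1 term is even
  expect_equal(conditional_hazard(t, 1, 0, 0, 0, 0, "nonph"),
               conditional_hazard(t, -1, 0, 0, 0, 0, "nonph"))
})

test_that("inverse-survival failure draws honour the edge cases", {
  lam <- matrix(0.05, 2, 10000)  # constant hazard on the fine grid
  expect_equal(
    draw_failure_times(lam, c(1 - 1e-12, 1e-300)), c(0, 100)
  )
})

test_that("forced constant hazard yields exponential failure times", {
  n <- 5000
  lam <- matrix(0.1, n, 10000)
  set.seed(23)
  u <- runif(n)
  tt <- draw_failure_times(lam, u)
  # discretisation puts T on a 0.01 grid; KS against Exp(0.1)
  ks <- suppressWarnings(ks.test(tt + 0.005, "pexp", 0.1))
  expect_gt(ks$p.value, 0.01)
})

test_that("censoring behaves at the rate extremes and calibrates to target", {
  set.seed(5)
  ft <- runif(2000, 0, 99)  # below the horizon so the cap plays no role
  none <- apply_censoring(ft, 1e-9)
  expect_gt(mean(none$delta), 0.999)
  all_c <- apply_censoring(ft, 1e6)
  expect_lt(mean(all_c$delta), 0.001)

  rate <- calibrate_censoring_rate("ph", seed = 3)
  expect_lt(abs(attr(rate, "achieved") - 0.20), 0.01)
})

test_that("the long-format generator writes a valid counting-process layout", {
  d <- sim_censored(censored_sim_config(60, "ph", censor_rate = 0.011, seed = 6))
  expect_true(all(c("id", "tstart", "tstop", "event", "x1", "x5") %in% names(d)))
  expect_silent(condhaz:::check_censored_long(d))
  # reproducible
  d2 <- sim_censored(censored_sim_config(60, "ph", censor_rate = 0.011, seed = 6))
  expect_identical(as.data.frame(d), as.data.frame(d2))
  # proportional-hazards construction: log-hazard differences between two
  # static profiles are time-constant
  s1 <- attr(d, "subjects")[1, ]
  t <- c(10, 40, 80)
  x1 <- eval_sim_covariates(s1, t)
  base <- log(conditional_hazard(t, x1$x1, x1$x2, 1, 2, 0.5, "ph")) -
    log(conditional_hazard(t, x1$x1, x1$x2, 0, 0, 0.1, "ph"))
  expect_equal(base, rep(base[1], 3))
})

test_that("mixture-error designs match their moments and supports", {
  d <- sim_uncensored(20000, "indep", 0.5, seed = 7)
  expect_true(all(abs(d$x1) <= 3))
  expect_true(all(d$x5 %in% 0:5))
  # E[eps] = 0 in the independent design: mean response equals mean m(x)
  m <- true_mean_uncensored(d, "indep", 0.5)
  expect_lt(abs(mean(d$y) - mean(m)), 4 * sd(d$y) / sqrt(20000))
  # reproducibility
  expect_identical(sim_uncensored(50, "corr", 1, seed = 3),
                   sim_uncensored(50, "corr", 1, seed = 3))
})

test_that("the closed-form true CDF matches Monte-Carlo draws", {
  x <- tibble::tibble(x1 = 0.8, x2 = 0.5, x3 = 0.4, x4 = 1, x5 = 2)
  for (setup in c("indep", "corr")) {
    set.seed(31)
    n <- 2e5
    x6 <- if (setup == "indep") rnorm(n, 1, 1) else
      rnorm(n, 1 + 0.5 * x$x1, sqrt(0.75))
    comp <- sample.int(3, n, replace = TRUE, prob = c(0.1, 0.7, 0.2))
    eps <- ifelse(comp == 1, rnorm(n, -2), ifelse(comp == 2, rnorm(n), 0.5 * x6^2))
    g <- if (setup == "indep") 0.5 else 0.5 * x$x1^2
    m <- x$x1^2 + x$x2 * x$x3 + x$x3 * x$x4 + x$x5
    ysim <- m + eps * g
    for (q in c(-0.5, 0, 0.5, 1, 2)) {
      expect_lt(
        abs(true_cdf_uncensored(m + q, x, setup, 0.5) - mean(ysim <= m + q)),
        0.005
      )
    }
  }
})

test_that("degenerate noise collapses the true CDF to a step at the mean", {
  x <- tibble::tibble(x1 = 0, x2 = 0.5, x3 = 0.4, x4 = 1, x5 = 2)  # g = c x1^2 = 0
  m <- x$x2 * x$x3 + x$x3 * x$x4 + x$x5
  expect_equal(true_cdf_uncensored(m - 1e-9, x, "corr", 0.5), 0)
  expect_equal(true_cdf_uncensored(m, x, "corr", 0.5), 1)
})

test_that("triangular tools and the sine designs are coherent", {
  expect_equal(ptriangular(0), 0.5)
  expect_equal(ptriangular(qtriangular(c(0.1, 0.5, 0.9))), c(0.1, 0.5, 0.9))
  set.seed(11)
  e <- rtriangular(1e5)
  expect_lt(abs(mean(e)), 3 * sd(e) / sqrt(1e5))
  expect_true(all(abs(e) <= 1))

  d <- sim_kernel_example(100, 1, seed = 2)
  # the true conditional median sits at the mean function
  expect_equal(
    true_cdf_kernel(2 * sin(3.1416 * d$x1), d), rep(0.5, 100)
  )
  d2 <- sim_kernel_example(10, 2, seed = 2)
  expect_true(all(c("x1", "x2") %in% names(d2)))
  expect_equal(
    true_cdf_kernel(2 * sin(3.1416 * d2$x1) + d2$x2, d2), rep(0.5, 10)
  )
})
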