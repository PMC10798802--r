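test_that("the network has the documented dense architecture", {
  net <- make_network(7, training_config(nodes = 64, seed = 1))
  n_par <- length(net$W1) + length(net$b1) + length(net$W2) +
    length(net$b2) + length(net$w3) + 1
  expect_equal(n_par, 7 * 64 + 64 + 64 * 64 + 64 + 64 + 1)
  expect_error(make_network(0), "at least 1")

  # finite output for finite input, and h == output bias when weights vanish
  X <- matrix(rnorm(30), 10, 3)
  net3 <- make_network(3, training_config(seed = 2))
  expect_true(all(is.finite(condhaz:::nn_forward_cpp(unclass(net3), X))))
  zero <- lapply(net3, function(w) w * 0)
  zero$b3 <- 1.75
  expect_equal(condhaz:::nn_forward_cpp(zero, X), rep(1.75, 10))
})

test_that("early stopping trains, records history and restores best weights", {
  d <- sim_uncensored(80, "indep", 0.5, seed = 5)
  tab1 <- expand_uncensored(d[1:40, ])
  tab2 <- expand_uncensored(d[41:80, ])
  fit <- train_early_stopping(tab1, tab2,
                              training_config(seed = 3, max_epochs = 40))
  hist <- fit$history[[1]]
  expect_equal(nrow(hist), fit$stopped_epoch)
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  expect_lte(fit$stopped_epoch - fit$best_epoch, 10)
  expect_equal(min(hist$val_loss), fit$best_val)
  # optimiser sanity: the best training loss improves on the first epoch
  expect_lte(min(hist$train_loss), hist$train_loss[1])
})

test_that("patience bounds the distance between best and stopping epoch", {
  d <- sim_uncensored(40, "indep", 0.5, seed = 8)
  tab1 <- expand_uncensored(d[1:20, ])
  tab2 <- expand_uncensored(d[21:40, ])
  fit <- train_early_stopping(
    tab1, tab2, training_config(seed = 1, patience = 1, max_epochs = 50)
  )
  expect_lte(fit$stopped_epoch - fit$best_epoch, 1)
})

test_that("swap-and-average averages the two networks' h outputs pointwise", {
  d <- sim_uncensored(60, "indep", 0.5, seed = 9)
  fit <- fit_hazard(d, "uncensored", training_config(seed = 4, max_epochs = 15))
  expect_length(fit$nets, 2)

  one <- fit; one$nets <- fit$nets[1]; one$std <- fit$std[[1]]
  two <- fit; two$nets <- fit$nets[2]; two$std <- fit$std[[2]]
  X <- matrix(rnorm(40), 8, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  tprev <- rnorm(8); tcur <- tprev + 1
  expect_equal(
    predict_h(fit, tprev, tcur, X),
    (predict_h(one, tprev, tcur, X) + predict_h(two, tprev, tcur, X)) / 2,
    tolerance = 1e-12
  )

  # identical nets average to themselves; opposite outputs cancel
  same <- fit; same$nets <- fit$nets[c(1, 1)]; same$std <- fit$std[c(1, 1)]
  expect_equal(predict_h(same, tprev, tcur, X),
               predict_h(one, tprev, tcur, X))
  flip <- fit$nets[[1]]
  flip$w3 <- -flip$w3; flip$b3 <- -flip$b3
  anti <- fit; anti$nets <- list(fit$nets[[1]], flip)
  anti$std <- fit$std[c(1, 1)]
  expect_equal(predict_h(anti, tprev, tcur, X), rep(0, 8), tolerance = 1e-12)
})

test_that("fits are deterministic given the seed and reload identically", {
  d <- sim_uncensored(50, "indep", 0.5, seed = 10)
  cfg <- training_config(seed = 6, max_epochs = 10)
  f1 <- fit_hazard(d, "uncensored", cfg)
  f2 <- fit_hazard(d, "uncensored", cfg)
  X <- as.matrix(d[1:5, -1])
  expect_equal(predict_h(f1, 0, 1, X), predict_h(f2, 0, 1, X),
               tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".rds")
  write_hazard_fit(f1, path)
  f3 <- read_hazard_fit(path)
  expect_equal(predict_h(f3, 0, 1, X), predict_h(f1, 0, 1, X))
})

test_that("fitted curves are monotone and bounded whatever the training", {
  d <- sim_uncensored(40, "corr", 1, seed = 11)
  fit <- fit_hazard(d, "uncensored",
                    training_config(seed = 2, max_epochs = 3))
  cdfs <- predict_cdfs(fit, d[1:6, ])
  for (cdf in cdfs) {
    expect_true(all(diff(cdf$cdf) >= -1e-12))
    expect_true(all(cdf$cdf >= 0 & cdf$cdf < 1))
    expect_equal(cdf$cdf[1], 1 / fit$n_train)
  }
})

test_that("hyperparameter search returns the singleton and breaks ties first", {
  d <- sim_uncensored(40, "indep", 0.5, seed = 12)
  base <- training_config(seed = 3, max_epochs = 5)
  single <- tune_hyperparameters(
    d, "uncensored",
    grid = list(nodes = 8, learning_rate = 0.01, batch_size = 50),
    config = base
  )
  expect_equal(single$nodes, 8L)
  expect_equal(single$batch_size, 50L)
  search <- attr(single, "search")
  expect_equal(nrow(search), 1)
  expect_error(
    tune_hyperparameters(d, "uncensored",
                         grid = list(nodes = numeric(0),
                                     learning_rate = 0.01, batch_size = 10)),
    "empty"
  )
})

test_that("tidy and glance summarise a fit", {
  d <- sim_uncensored(40, "indep", 0.5, seed = 13)
  fit <- fit_hazard(d, "uncensored", training_config(seed = 1, max_epochs = 5))
  td <- tidy(fit)
  expect_true(all(c("network", "epoch", "set", "loss") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_networks, 2)
  expect_equal(gl$mode, "uncensored")
  expect_s3_class(autoplot(fit), "ggplot")
})
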