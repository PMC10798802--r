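#' Replicated uncensored-regression experiment
#'
#' Runs the full pipeline on freshly simulated mixture-error data
#' ([sim_uncensored()]): fit the hazard network by swap-and-average, predict
#' conditional means, equal-tailed 90%/95% predictive intervals and
#' percentile calibration on an independent test set, and (optionally) fit
#' the L2-loss baseline on the same training data. One row per replication.
#'
#' @param setup `"indep"` or `"corr"`.
#' @param n training-sample size (split 1:1 into training and validation).
#' @param c noise scale.
#' @param n_test test-set size.
#' @param reps number of independent replications.
#' @param seed integer seed; replication `r` uses seed `seed + 1000 r`.
#' @param config base [training_config()] (its seed is overridden per
#'   replication).
#' @param targets probabilities for the percentile-calibration columns.
#' @param include_l2 also fit the L2 baseline and report its errors.
#' @return Tibble with one row per replication: `cov90`, `cov95`, `mean_sq`,
#'   `median_sq`, `l2_mean_sq`, `l2_median_sq` and calibration columns
#'   `calib_<p>`.
#' @export
run_uncensored_experiment <- function(setup = c("indep", "corr"), n = 1000,
                                      c = 0.5, n_test = 500, reps = 5,
                                      seed = 1, config = training_config(),
                                      targets = seq(0.1, 0.9, 0.1),
                                      include_l2 = TRUE) {
  setup <- match.arg(setup)
  purrr::map(seq_len(reps), function(r) {
    s <- (seed + 1000L * r) %% .Machine$integer.max
    train <- sim_uncensored(n, setup, c, seed = s)
    test <- sim_uncensored(n_test, setup, c, seed = s + 499L)
    cfg <- config
    cfg$seed <- s
    fit <- fit_hazard(train, "uncensored", cfg)

    cdfs <- predict_cdfs(fit, test)
    means <- purrr::map_dbl(cdfs, conditional_mean)
    iv90 <- purrr::map(cdfs, predictive_interval, level = 0.90) |>
      purrr::map(tibble::as_tibble_row) |> dplyr::bind_rows()
    iv95 <- purrr::map(cdfs, predictive_interval, level = 0.95) |>
      purrr::map(tibble::as_tibble_row) |> dplyr::bind_rows()
    err <- prediction_errors(means, test$y)
    calib <- percentile_calibration(cdfs, test$y, targets)

    out <- tibble(
      rep = r,
      cov90 = coverage_rate(iv90, test$y),
      cov95 = coverage_rate(iv95, test$y),
      mean_sq = err$mean_sq, median_sq = err$median_sq
    )
    if (include_l2) {
      l2 <- fit_l2_network(train, cfg)
      l2_err <- prediction_errors(predict(l2, test), test$y)
      out$l2_mean_sq <- l2_err$mean_sq
      out$l2_median_sq <- l2_err$median_sq
    }
    dplyr::bind_cols(
      out,
      stats::setNames(as.list(calib$empirical), paste0("calib_", targets))
    )
  }) |>
    dplyr::bind_rows()
}

#' Replicated kernel-comparison experiment
#'
#' Scores the hazard-network estimator and the cross-validated
#' Nadaraya-Watson estimator by MADE on the sine-regression designs
#' ([sim_kernel_example()]), evaluated on the regular grid of
#' [kernel_eval_grid()] restricted to points with true F in [0.001, 0.999].
#'
#' @param dims 1 or 2 covariates.
#' @param n training-sample size.
#' @param reps number of replications.
#' @param seed integer seed.
#' @param config base [training_config()].
#' @return Tibble with one row per replication: `made_nn`, `made_nw`.
#' @export
run_kernel_experiment <- function(dims = 1, n = 1000, reps = 10, seed = 1,
                                  config = training_config()) {
  grid <- kernel_eval_grid(dims)
  covars <- setdiff(names(grid), "y")
  ux <- dplyr::distinct(grid[, covars, drop = FALSE])
  yu <- unique(grid$y)
  i_x <- rep(seq_len(nrow(ux)), each = length(yu))
  i_y <- rep(seq_along(yu), times = nrow(ux))
  f_true <- true_cdf_kernel(grid$y, grid)

  purrr::map(seq_len(reps), function(r) {
    s <- (seed + 1000L * r) %% .Machine$integer.max
    train <- sim_kernel_example(n, dims, seed = s)
    cfg <- config
    cfg$seed <- s
    fit <- fit_hazard(train, "uncensored", cfg)
    cdfs <- predict_cdfs(fit, ux)
    Fnn <- t(vapply(cdfs, function(cdf) eval_cdf(cdf, yu), numeric(length(yu))))

    bw <- cv_bandwidth(train, seed = s + 11L)
    Fnw <- nw_cdf(nw_estimator(train, bw), ux, yu)

    tibble(
      rep = r,
      made_nn = made(Fnn[cbind(i_x, i_y)], f_true),
      made_nw = made(Fnw[cbind(i_x, i_y)], f_true)
    )
  }) |>
    dplyr::bind_rows()
}
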