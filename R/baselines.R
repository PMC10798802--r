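#' L2-loss network baseline with residual-shift CDF
#'
#' The conventional neural regression baseline: the same architecture and
#' training protocol as the hazard network (1:1 split, early stopping,
#' swap-and-average) but minimising mean squared error on `(x -> y)`, so the
#' network estimates the conditional mean. Its conditional distribution
#' estimate shifts the empirical distribution of training residuals to the
#' estimated mean -- valid only when the errors are i.i.d. and uncorrelated
#' with the mean.
#'
#' @param data data frame with `y` and covariates.
#' @param config a [training_config()].
#' @param swap_average as in [fit_hazard()].
#' @return An `l2_fit` with the fitted mean function and sorted training
#'   residuals.
#' @export
fit_l2_network <- function(data, config = training_config(),
                           swap_average = TRUE) {
  data <- as_tibble(data)
  if (!"y" %in% names(data)) abort("`data` needs a `y` column.")
  covars <- setdiff(names(data), "y")
  n <- nrow(data)
  if (n < 4) abort("need at least 4 observations to split 1:1.")

  set.seed(config$seed %% .Machine$integer.max)
  shuffled <- sample(n)
  half1 <- shuffled[seq_len(floor(n / 2))]
  half2 <- setdiff(shuffled, half1)

  fit_one <- function(tr_rows, va_rows, seed_off) {
    Xtr <- as.matrix(data[tr_rows, covars, drop = FALSE])
    Xva <- as.matrix(data[va_rows, covars, drop = FALSE])
    std <- standardizer(Xtr)
    cfg <- config
    cfg$seed <- (config$seed + seed_off) %% .Machine$integer.max
    net <- make_network(length(covars), cfg)
    res <- nn_train_cpp(
      apply_std(Xtr, std), rep(0, length(tr_rows)), data$y[tr_rows],
      apply_std(Xva, std), rep(0, length(va_rows)), data$y[va_rows],
      unclass(net), 1L, cfg$learning_rate, cfg$batch_size, cfg$patience,
      cfg$max_epochs, -Inf, Inf, (cfg$seed + 7L) %% .Machine$integer.max
    )
    list(net = res[c("W1", "b1", "W2", "b2", "w3", "b3")], std = std,
         history = tibble(
           epoch = seq_along(res$train_loss),
           train_loss = res$train_loss / length(tr_rows),
           val_loss = res$val_loss / length(va_rows)
         ))
  }
  fits <- list(fit_one(half1, half2, 101L))
  if (swap_average) fits <- c(fits, list(fit_one(half2, half1, 202L)))

  obj <- structure(
    list(
      nets = purrr::map(fits, "net"), stds = purrr::map(fits, "std"),
      covariates = covars, history = purrr::map(fits, "history"),
      residuals = NULL
    ),
    class = "l2_fit"
  )
  obj$residuals <- sort(data$y - predict(obj, data))
  obj
}

#' @export
predict.l2_fit <- function(object, newdata, ...) {
  X <- as.matrix(as_tibble(newdata)[, object$covariates, drop = FALSE])
  preds <- purrr::map2(object$nets, object$stds, function(net, std) {
    nn_forward_cpp(net, apply_std(X, std))
  })
  Reduce(`+`, preds) / length(preds)
}

#' @export
print.l2_fit <- function(x, ...) {
  cat(sprintf(
    "<l2_fit> %d network(s), %d covariates, %d training residuals\n",
    length(x$nets), length(x$covariates), length(x$residuals)
  ))
  invisible(x)
}

#' Residual-shift conditional distribution estimate
#'
#' `F(y | x) = (1/n) sum_i 1(r_i <= y - m(x))`: the empirical CDF of the
#' training residuals recentred at the estimated conditional mean.
#'
#' @param fit an [fit_l2_network()] result.
#' @param newdata covariate data frame (one row per prediction).
#' @param y response values; either one per row of `newdata` or a common
#'   vector evaluated for every row.
#' @return If `y` matches `newdata` row-wise, a vector of `F(y_i | x_i)`;
#'   otherwise a matrix with one row per `newdata` row and one column per `y`.
#' @export
residual_shift_cdf <- function(fit, newdata, y) {
  stopifnot(inherits(fit, "l2_fit"))
  mhat <- predict(fit, newdata)
  r <- fit$residuals
  ecdf_at <- function(v) findInterval(v + 1e-12, r) / length(r)
  if (length(y) == length(mhat)) {
    ecdf_at(y - mhat)
  } else {
    t(vapply(mhat, function(m) ecdf_at(y - m), numeric(length(y))))
  }
}

#' Nadaraya-Watson conditional distribution estimator
#'
#' `F(y | x) = sum_i K_h(x - x_i) 1(y_i <= y) / sum_i K_h(x - x_i)` with a
#' Gaussian product kernel across covariate dimensions (no zero-mass failures
#' in sparse regions).
#'
#' @param data training data frame with `y` and covariates.
#' @param bandwidth positive bandwidth, one per covariate dimension
#'   (recycled).
#' @return An `nw_estimator`.
#' @export
nw_estimator <- function(data, bandwidth) {
  data <- as_tibble(data)
  covars <- setdiff(names(data), "y")
  stopifnot(length(covars) >= 1, all(bandwidth > 0))
  structure(
    list(
      X = as.matrix(data[, covars, drop = FALSE]), y = data$y,
      bandwidth = rep_len(bandwidth, length(covars)), covariates = covars
    ),
    class = "nw_estimator"
  )
}

nw_weights <- function(est, Xnew) {
  W <- matrix(1, nrow(Xnew), nrow(est$X))
  for (d in seq_len(ncol(est$X))) {
    W <- W * outer(Xnew[, d], est$X[, d], function(a, b) {
      stats::dnorm((a - b) / est$bandwidth[d])
    })
  }
  W
}

#' Evaluate the Nadaraya-Watson conditional CDF
#'
#' @param est an [nw_estimator()].
#' @param newdata covariate data frame.
#' @param y response evaluation points (common to all rows).
#' @return Matrix of `F(y | x)`: one row per `newdata` row, one column per
#'   `y`.
#' @export
nw_cdf <- function(est, newdata, y) {
  stopifnot(inherits(est, "nw_estimator"))
  Xnew <- as.matrix(as_tibble(newdata)[, est$covariates, drop = FALSE])
  W <- nw_weights(est, Xnew)
  mass <- rowSums(W)
  if (any(mass <= 0)) abort("zero kernel mass at an evaluation point.")
  ind <- outer(est$y, y, `<=`)
  (W %*% ind) / mass
}

#' Cross-validated bandwidth for the Nadaraya-Watson CDF
#'
#' K-fold cross-validation minimising the mean squared difference between the
#' held-out indicator `1(y_i <= y)` and the estimated `F(y | x_i)`, averaged
#' over 21 response-grid points spanning the training range (a discretised
#' CRPS). Candidates are per-dimension bandwidths `mult * sd(x_d) * n^(-1/5)`;
#' ties go to the smaller bandwidth.
#'
#' @param data training data frame with `y` and covariates.
#' @param k number of folds.
#' @param grid increasing multipliers for the reference bandwidth.
#' @param seed integer seed for fold assignment.
#' @return The selected bandwidth vector; the search table is in attribute
#'   `"search"`.
#' @export
cv_bandwidth <- function(data, k = 5,
                         grid = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4),
                         seed = 1) {
  if (length(grid) == 0) abort("empty bandwidth grid.")
  data <- as_tibble(data)
  covars <- setdiff(names(data), "y")
  n <- nrow(data)
  base <- apply(as.matrix(data[, covars, drop = FALSE]), 2, sd) * n^(-1 / 5)
  base[base < 1e-8] <- 1e-8
  ygrid <- seq(min(data$y), max(data$y), length.out = 21)

  set.seed(seed %% .Machine$integer.max)
  fold <- sample(rep_len(seq_len(k), n))
  scores <- purrr::map_dbl(grid, function(mult) {
    errs <- purrr::map_dbl(seq_len(k), function(f) {
      est <- nw_estimator(data[fold != f, , drop = FALSE], mult * base)
      Fh <- nw_cdf(est, data[fold == f, , drop = FALSE], ygrid)
      ind <- outer(data$y[fold == f], ygrid, `<=`)
      mean((ind - Fh)^2)
    })
    mean(errs)
  })
  best <- which.min(scores)  # first minimum = smallest bandwidth on ties
  structure(grid[best] * base,
    search = tibble(multiplier = grid, cv_mse = scores)
  )
}
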