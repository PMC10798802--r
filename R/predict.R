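#' Predicted conditional distribution functions for new covariates
#'
#' Evaluates the fitted log-hazard on the training grid for every row of
#' `newdata` in one batched forward pass and assembles the step-function
#' distribution estimates.
#'
#' @param fit an uncensored-mode `hazard_fit`.
#' @param newdata data frame of covariates (training columns).
#' @return List of [cond_cdf] objects, one per row.
#' @export
predict_cdfs <- function(fit, newdata) {
  stopifnot(inherits(fit, "hazard_fit"), fit$mode == "uncensored")
  X <- as.matrix(as_tibble(newdata)[, fit$covariates, drop = FALSE])
  pts <- fit$grid$points
  m <- length(pts)
  n_new <- nrow(X)
  if (m < 2) {
    return(purrr::map(seq_len(n_new), function(i) {
      new_cond_cdf(pts, 1 / fit$n_train, "uncensored", fit$n_train)
    }))
  }
  # subject-major rows: subject i occupies rows (i-1)(m-1) + (1 .. m-1)
  h <- predict_h(
    fit,
    tprev = rep(pts[-m], n_new),
    tcur = rep(pts[-1], n_new),
    X = X[rep(seq_len(n_new), each = m - 1), , drop = FALSE]
  )
  clamp <- fit$config$clamp
  inc <- exp(pmin(pmax(h, clamp[1]), clamp[2])) * rep(diff(pts), n_new)
  cum <- apply(matrix(inc, nrow = m - 1), 2, cumsum)
  cum <- matrix(cum, nrow = m - 1)
  n <- fit$n_train
  purrr::map(seq_len(n_new), function(i) {
    Fv <- c(1 / n, 1 - (1 - 1 / n) * pmax(exp(-cum[, i]), 1e-15))
    new_cond_cdf(pts, Fv, "uncensored", n)
  })
}

#' Predicted conditional survival curves for new subjects
#'
#' Reconstructs `S(t | path)` on the fitted grid for each subject of a
#' long-format data set; covariate values beyond a subject's last interval are
#' carried forward (needed when scoring a subject at times after its own
#' observed time).
#'
#' @param fit a censored-mode `hazard_fit`.
#' @param newdata long-format data (`id`, `tstart`, `tstop`, covariates;
#'   `event` optional).
#' @return Named list of [cond_cdf] objects, one per subject.
#' @export
predict_survival <- function(fit, newdata) {
  stopifnot(inherits(fit, "hazard_fit"), fit$mode == "censored")
  newdata <- dplyr::arrange(as_tibble(newdata), .data$id, .data$tstart)
  pts <- fit$grid$points
  m <- length(pts)
  by_id <- split(seq_len(nrow(newdata)), newdata$id)

  Xblocks <- purrr::map(by_id, function(rows) {
    seg <- pmin(
      findInterval(pts, newdata$tstop[rows], left.open = TRUE) + 1L,
      length(rows)
    )
    as.matrix(newdata[rows[seg], fit$covariates, drop = FALSE])
  })
  h <- predict_h(
    fit,
    tprev = rep(c(0, pts[-m]), length(by_id)),
    tcur = rep(pts, length(by_id)),
    X = do.call(rbind, Xblocks)
  )
  clamp <- fit$config$clamp
  inc <- exp(pmin(pmax(h, clamp[1]), clamp[2])) * rep(diff(c(0, pts)), length(by_id))
  cum <- matrix(apply(matrix(inc, nrow = m), 2, cumsum), nrow = m)
  out <- purrr::map(seq_along(by_id), function(i) {
    surv <- pmax(exp(-cum[, i]), 1e-15)
    new_cond_cdf(pts, 1 - surv, "censored")
  })
  names(out) <- names(by_id)
  out
}

#' Predict from a fitted hazard network
#'
#' For uncensored fits: conditional means, equal-tailed predictive intervals,
#' quantiles, or the full distribution estimates. For censored fits the
#' survival curves are returned (see [predict_survival()]).
#'
#' @param object a `hazard_fit`.
#' @param newdata covariate data frame (uncensored) or long-format data
#'   (censored).
#' @param type one of `"mean"`, `"interval"`, `"quantile"`, `"cdf"`.
#' @param level interval coverage level.
#' @param probs quantile probabilities.
#' @param ... unused.
#' @return A tibble (one row per prediction) for `"mean"`, `"interval"` and
#'   `"quantile"`; a list of [cond_cdf] for `"cdf"`.
#' @export
predict.hazard_fit <- function(object, newdata,
                               type = c("mean", "interval", "quantile", "cdf"),
                               level = 0.9, probs = 0.5, ...) {
  type <- match.arg(type)
  if (object$mode == "censored") {
    return(predict_survival(object, newdata))
  }
  cdfs <- predict_cdfs(object, newdata)
  switch(type,
    cdf = cdfs,
    mean = tibble(.mean = purrr::map_dbl(cdfs, conditional_mean)),
    interval = purrr::map(cdfs, function(cdf) {
      q <- predictive_interval(cdf, level)
      tibble(lower = q[["lower"]], upper = q[["upper"]])
    }) |> dplyr::bind_rows(),
    quantile = purrr::map(cdfs, function(cdf) {
      q <- quantile(cdf, probs)
      tibble::as_tibble_row(stats::setNames(q, paste0("q", probs)))
    }) |> dplyr::bind_rows()
  )
}
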