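#' Kaplan-Meier estimate of the censoring-time survival function
#'
#' Fits the product-limit estimator to `(y, 1 - delta)` -- censorings are the
#' "events". Used as the IPCW weight in [brier_score()] and [binomial_ll()].
#'
#' @param y observed times.
#' @param delta event indicators (1 = failure, 0 = censored).
#' @return A `censoring_survival` object; evaluate with [eval_G()].
#' @export
km_censoring <- function(y, delta) {
  stopifnot(length(y) == length(delta), all(delta %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(y, 1 - delta) ~ 1)
  drop <- fit$n.event > 0
  structure(
    list(time = fit$time[drop], surv = fit$surv[drop]),
    class = "censoring_survival"
  )
}

#' Evaluate a censoring-survival estimate
#'
#' @param G a [km_censoring()] result.
#' @param t times.
#' @param left if `TRUE` return the left limit `G(t-)` -- the standard IPCW
#'   convention when weighting a subject by its own observed time, preventing
#'   a censoring event from down-weighting itself.
#' @export
eval_G <- function(G, t, left = FALSE) {
  stopifnot(inherits(G, "censoring_survival"))
  idx <- findInterval(t, G$time, left.open = left)
  c(1, G$surv)[idx + 1L]
}

#' Time-dependent concordance index
#'
#' Empirical probability that predicted survival orders a comparable pair of
#' subjects concordantly with their event times: over pairs with
#' `delta_i = 1` and `y_i < y_j` (tied event times are not comparable), the
#' proportion with `S(y_i | x_i) < S(y_i | x_j)`; ties in predicted survival
#' count 1/2, so a predictor that ignores the covariates scores 0.5.
#'
#' @param surv_matrix matrix with `surv_matrix[i, j]` = predicted
#'   `S(y_i | x_j)`.
#' @param y observed times.
#' @param delta event indicators.
#' @return The C-index in `[0, 1]`.
#' @export
c_index_td <- function(surv_matrix, y, delta) {
  n <- length(y)
  stopifnot(nrow(surv_matrix) == n, ncol(surv_matrix) == n)
  num <- 0; den <- 0
  for (i in which(delta == 1)) {
    js <- which(y > y[i])
    if (length(js) == 0) next
    diffs <- surv_matrix[i, js] - surv_matrix[i, i]
    num <- num + sum(diffs > 0) + 0.5 * sum(diffs == 0)
    den <- den + length(js)
  }
  if (den == 0) abort("no comparable pairs for the C-index.")
  num / den
}

#' IPCW Brier score and binomial log-likelihood at a fixed time
#'
#' `brier_score()` computes
#' `BS(t) = (1/n) sum_i { S(t|x_i)^2 I(y_i <= t, delta_i = 1) / G(y_i-) +
#' (1 - S(t|x_i))^2 I(y_i > t) / G(t) }`; `binomial_ll()` replaces the squared
#' errors by `log(1 - S)` and `log(S)`. Probabilities inside the logs are
#' clipped below at `clip` to stay finite (a warning reports clipping); terms
#' whose censoring weight is zero are dropped with a warning.
#'
#' @param t evaluation time.
#' @param surv predicted `S(t | x_i)`, one per subject.
#' @param y,delta observed times and event indicators.
#' @param G a [km_censoring()] estimate on the evaluation set.
#' @param clip lower clipping bound for probabilities inside logs.
#' @return A single number.
#' @export
brier_score <- function(t, surv, y, delta, G) {
  w <- ipcw_weights(t, y, delta, G)
  mean(surv^2 * w$w_event + (1 - surv)^2 * w$w_alive)
}

#' @rdname brier_score
#' @export
binomial_ll <- function(t, surv, y, delta, G, clip = 1e-12) {
  w <- ipcw_weights(t, y, delta, G)
  s <- pmin(pmax(surv, clip), 1 - clip)
  if (any((s != surv) & (w$w_event + w$w_alive > 0))) {
    warn("survival probabilities clipped inside log().")
  }
  mean(log(1 - s) * w$w_event + log(s) * w$w_alive)
}

ipcw_weights <- function(t, y, delta, G) {
  event_by_t <- as.numeric(y <= t & delta == 1)
  alive <- as.numeric(y > t)
  g_own <- eval_G(G, y, left = TRUE)
  g_t <- eval_G(G, t)
  bad <- (event_by_t > 0 & g_own <= 0) | (alive > 0 & g_t <= 0)
  if (any(bad)) {
    warn(sprintf("%d term(s) dropped: zero censoring weight.", sum(bad)))
    event_by_t[bad] <- 0
    alive[bad] <- 0
  }
  list(
    w_event = ifelse(event_by_t > 0, event_by_t / g_own, 0),
    w_alive = ifelse(alive > 0, alive / g_t, 0)
  )
}

#' Time-average a score curve by trapezoidal integration
#'
#' @param times increasing evaluation times spanning the test set's observed
#'   range.
#' @param values score values on `times`.
#' @return The integral divided by the range length.
#' @export
integrate_scores <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (max(times) - min(times) <= 0) abort("degenerate integration range.")
  k <- length(times)
  sum(diff(times) * (values[-1] + values[-k]) / 2) / (max(times) - min(times))
}

#' Mean absolute deviation error between estimated and true CDF values
#'
#' Mean of `|Fhat - F|` over evaluation points where the true `F` lies in
#' `[0.001, 0.999]` (the tails are excluded, where both estimates are pinned
#' near 0/1).
#'
#' @param f_hat,f_true aligned vectors of estimated and true conditional CDF
#'   values.
#' @export
made <- function(f_hat, f_true) {
  stopifnot(length(f_hat) == length(f_true))
  keep <- f_true >= 0.001 & f_true <= 0.999
  if (!any(keep)) abort("no evaluation point has true F in [0.001, 0.999].")
  mean(abs(f_hat[keep] - f_true[keep]))
}

#' Squared prediction errors and interval coverage
#'
#' @param predicted predicted conditional means.
#' @param y observed responses.
#' @return `prediction_errors()`: tibble with `mean_sq` and `median_sq`.
#' @export
prediction_errors <- function(predicted, y) {
  stopifnot(length(predicted) == length(y))
  e2 <- (predicted - y)^2
  tibble(mean_sq = mean(e2), median_sq = median(e2))
}

#' @rdname prediction_errors
#' @param intervals data frame or matrix with columns `lower`, `upper`.
#' @return `coverage_rate()`: the fraction of `y` inside its interval.
#' @export
coverage_rate <- function(intervals, y) {
  intervals <- as.data.frame(intervals)
  stopifnot(nrow(intervals) == length(y),
            all(c("lower", "upper") %in% names(intervals)))
  mean(y >= intervals$lower & y <= intervals$upper)
}

#' Percentile calibration of estimated conditional CDFs
#'
#' For each target probability `p`, computes each test subject's estimated
#' `p`-quantile and returns the frequency of subjects whose response falls at
#' or below it. A well-calibrated estimator returns frequencies close to the
#' targets (probability-integral transform).
#'
#' @param cdfs list of [cond_cdf] objects, one per test subject.
#' @param y test responses, aligned with `cdfs`.
#' @param target_probs probabilities in (0, 1).
#' @return Tibble `target`, `empirical`.
#' @export
percentile_calibration <- function(cdfs, y, target_probs = seq(0.1, 0.9, 0.1)) {
  stopifnot(length(cdfs) == length(y), all(target_probs > 0 & target_probs < 1))
  emp <- purrr::map_dbl(target_probs, function(p) {
    q <- purrr::map_dbl(cdfs, function(cdf) quantile(cdf, p))
    mean(y <= q)
  })
  tibble(target = target_probs, empirical = emp)
}

#' Censored-data score panel on a test set
#'
#' Scores a fitted hazard model on held-out censored data: time-dependent
#' C-index, Brier and binomial log-likelihood curves on an equally spaced
#' grid between the test set's minimum and maximum observed times (100 points
#' by default), and their time-averaged IBS / IBLL.
#'
#' @param fit a `hazard_fit` (censored mode).
#' @param test long-format censored test data.
#' @param n_times integration-grid resolution.
#' @return A `score_panel`: list with `c_index`, `ibs`, `ibll` and the
#'   per-time `curves` tibble; `glance()` returns the scalars.
#' @export
score_panel <- function(fit, test, n_times = 100) {
  stopifnot(inherits(fit, "hazard_fit"), fit$mode == "censored")
  curves <- predict_survival(fit, test)
  subj <- censored_outcomes(test)
  y <- subj$y; delta <- subj$delta
  n <- length(y)

  # S[i, j] = Shat(y_i | x_j)
  Smat <- vapply(curves, function(cdf) 1 - eval_cdf(cdf, y), numeric(n))
  cidx <- c_index_td(Smat, y, delta)

  G <- km_censoring(y, delta)
  tgrid <- seq(min(y), max(y), length.out = n_times)
  St <- vapply(curves, function(cdf) 1 - eval_cdf(cdf, tgrid),
               numeric(length(tgrid)))
  msgs <- character()
  curves_val <- withCallingHandlers(
    {
      bs <- vapply(seq_along(tgrid),
                   function(k) brier_score(tgrid[k], St[k, ], y, delta, G),
                   numeric(1))
      bll <- vapply(seq_along(tgrid),
                    function(k) binomial_ll(tgrid[k], St[k, ], y, delta, G),
                    numeric(1))
      list(bs = bs, bll = bll)
    },
    warning = function(w) {
      msgs <<- union(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  bs <- curves_val$bs
  bll <- curves_val$bll
  for (m in msgs) warn(m)  # each distinct warning once, not per time point
  structure(
    list(
      c_index = cidx,
      ibs = integrate_scores(tgrid, bs),
      ibll = integrate_scores(tgrid, bll),
      curves = tibble(time = tgrid, brier = bs, bll = bll)
    ),
    class = "score_panel"
  )
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf(
    "<score_panel> C-index %.4f | IBS %.4f | IBLL %.4f (%d time points)\n",
    x$c_index, x$ibs, x$ibll, nrow(x$curves)
  ))
  invisible(x)
}

#' @export
glance.score_panel <- function(x, ...) {
  tibble(c_index = x$c_index, ibs = x$ibs, ibll = x$ibll)
}

#' @export
tidy.score_panel <- function(x, ...) x$curves

#' @export
autoplot.score_panel <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$curves, c("brier", "bll"),
    names_to = "score", values_to = "value"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$score), scales = "free_y")
}

#' K-fold cross-validated evaluation of the censored-data pipeline
#'
#' Assigns subjects to `k` folds by a seeded shuffle; for each fold, fits the
#' swap-and-average estimator on the remaining subjects (which internally
#' supplies training and validation halves) and scores the held-out fold with
#' [score_panel()]. The held-out data are used only as the test set.
#'
#' @param data long-format censored data.
#' @param k number of folds.
#' @param config a [training_config()].
#' @param n_times integration-grid resolution per fold.
#' @return Tibble of per-fold metrics; fold-averaged metrics in attribute
#'   `"summary"`. Folds where a score is undefined (e.g. no comparable pairs
#'   for the C-index in a tiny fold) yield `NA` with a warning.
#' @export
cross_validate <- function(data, k = 5, config = training_config(),
                           n_times = 100) {
  if (k < 2) abort("`k` must be at least 2.")
  ids <- unique(data$id)
  if (length(ids) < k) abort("fewer subjects than folds.")
  set.seed(config$seed %% .Machine$integer.max)
  fold <- sample(rep_len(seq_len(k), length(ids)))
  names(fold) <- as.character(ids)

  res <- purrr::map(seq_len(k), function(f) {
    test_ids <- ids[fold[as.character(ids)] == f]
    fit <- fit_hazard(
      data[!data$id %in% test_ids, , drop = FALSE], "censored", config
    )
    panel <- tryCatch(
      score_panel(fit, data[data$id %in% test_ids, , drop = FALSE], n_times),
      error = function(e) {
        warn(sprintf("fold %d: %s", f, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(panel)) {
      tibble(fold = f, c_index = NA_real_, ibs = NA_real_, ibll = NA_real_)
    } else {
      dplyr::mutate(glance(panel), fold = f, .before = 1)
    }
  })
  out <- dplyr::bind_rows(res)
  attr(out, "summary") <- dplyr::summarise(
    out,
    c_index = mean(.data$c_index, na.rm = TRUE),
    ibs = mean(.data$ibs, na.rm = TRUE),
    ibll = mean(.data$ibll, na.rm = TRUE)
  )
  out
}

censored_outcomes <- function(data) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(data), .data$id),
    y = max(.data$tstop), delta = .data$event[which.max(.data$tstop)],
    .groups = "drop"
  )
}
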