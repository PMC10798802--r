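#' Discretised negative log-likelihood losses
#'
#' `censored_loss()` evaluates the discretised full-likelihood loss for
#' right-censored data,
#' \deqn{loss(h) = \frac1n \sum_i \sum_j I(t_j \le y_i)
#'   \{ e^{h(t_j, x_i(t_j))} (t_j - t_{j-1}) - h(t_j, x_i(t_j))\,\delta_{ij} \},}
#' with `t_0 = 0`, given one `h` value per expanded-table row.
#' `uncensored_loss()` is the analogue for a continuous response where the sum
#' runs over `j >= 2` only (the excluded first rows carry the fixed `1/n` point
#' mass) and the constant `-log(1 - 1/n)` term is dropped.
#'
#' `h` is clamped to `clamp` inside the exponential as a numerical guard:
#' unconstrained network outputs can transiently explode during training. The
#' linear `h * delta` term is not clamped.
#'
#' @param h numeric vector, one value of the log conditional hazard per row of
#'   `table` (values on excluded rows are ignored).
#' @param table an `expanded_table` from [expand_censored()] or
#'   [expand_uncensored()].
#' @param clamp length-2 numeric, bounds applied to `h` inside `exp()`.
#' @return A single number: the per-subject averaged loss.
#' @export
censored_loss <- function(h, table, clamp = c(-30, 30)) {
  check_table(table, "censored")
  expanded_loss(h, table, clamp)
}

#' @rdname censored_loss
#' @export
uncensored_loss <- function(h, table, clamp = c(-30, 30)) {
  check_table(table, "uncensored")
  expanded_loss(h, table, clamp)
}

expanded_loss <- function(h, table, clamp) {
  if (length(h) != nrow(table)) {
    abort("`h` must have one value per row of `table`.")
  }
  keep <- !table$excluded
  h <- h[keep]
  width <- (table$tstop - table$tstart)[keep]
  delta <- table$delta[keep]
  if (length(h) == 0) return(0)
  hc <- pmin(pmax(h, clamp[1]), clamp[2])
  sum(exp(hc) * width - h * delta) / table_n(table)
}

check_table <- function(table, mode) {
  if (!inherits(table, "expanded_table") || !identical(table_mode(table), mode)) {
    abort(sprintf("`table` must be a %s-mode expanded_table.", mode))
  }
}
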