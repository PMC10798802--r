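#' Partition the time axis by the observed times
#'
#' The estimation grid is the set of unique sorted observed times from the
#' training set. In censored (survival) mode the integration of the cumulative
#' hazard starts at time zero; in uncensored mode the response lives on the
#' whole real line, the integral notionally starts at minus infinity, and the
#' interval ending at the first grid point is handled separately (it carries a
#' point mass of 1/n and is excluded from the loss).
#'
#' Tied observed times are collapsed to a single grid point: a duplicated time
#' would create a zero-width interval that contributes nothing to the
#' discretised likelihood.
#'
#' @param times numeric vector of observed times (censored mode) or responses
#'   (uncensored mode).
#' @param mode `"censored"` or `"uncensored"`.
#' @return A `time_grid` object: list with `points` (strictly increasing) and
#'   `origin` (`"zero"` or `"minus_infinity"`).
#' @examples
#' build_time_grid(c(2, 5, 5, 7), "censored")
#' @export
build_time_grid <- function(times, mode = c("censored", "uncensored")) {
  mode <- match.arg(mode)
  if (length(times) == 0) {
    abort("`times` must be non-empty.")
  }
  if (!all(is.finite(times))) {
    abort("`times` must be finite.")
  }
  if (mode == "censored" && any(times < 0)) {
    abort("observed times must be non-negative in censored mode.")
  }
  structure(
    list(
      points = sort(unique(as.numeric(times))),
      origin = if (mode == "censored") "zero" else "minus_infinity",
      mode = mode
    ),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %d points on [%g, %g], origin %s (%s mode)\n",
    length(x$points), min(x$points), max(x$points), x$origin, x$mode
  ))
  invisible(x)
}

# Interval widths t_j - t_{j-1}; the first width uses the origin (0 in
# censored mode, NA in uncensored mode where that interval is excluded).
grid_widths <- function(grid) {
  pts <- grid$points
  if (grid$origin == "zero") {
    diff(c(0, pts))
  } else {
    c(NA_real_, diff(pts))
  }
}
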