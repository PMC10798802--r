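#' Left-continuous step-function covariate path
#'
#' A time-varying covariate path stored as a step function: segment `j` covers
#' the half-open interval `(breaks[j-1], breaks[j]]` (with `breaks[0] = 0`) and
#' carries one covariate vector. Evaluation is left-continuous with right
#' limits, matching the convention that the hazard at `t` depends on the
#' covariates in force at `t`; a value that jumps at `q` still returns the
#' pre-jump value when evaluated at `q` itself.
#'
#' @param breaks increasing positive segment end times; the path is defined on
#'   `[0, max(breaks)]`.
#' @param values numeric matrix with one row per segment (or a vector for a
#'   single covariate).
#' @return A `covariate_path` object.
#' @examples
#' p <- covariate_path(c(2, 5), rbind(c(0, 1), c(1, 1)))
#' eval_path(p, c(0, 2, 2.5, 5))
#' @export
covariate_path <- function(breaks, values) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  breaks <- as.numeric(breaks)
  if (length(breaks) != nrow(values)) {
    abort("`breaks` must have one entry per row of `values`.")
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("`breaks` must be strictly increasing.")
  }
  if (any(breaks <= 0)) {
    abort("`breaks` must be positive (the path starts at time 0).")
  }
  structure(list(breaks = breaks, values = values), class = "covariate_path")
}

#' Evaluate a covariate path at given times
#'
#' @param path a [covariate_path()].
#' @param t numeric vector of times in `[0, max(breaks)]`.
#' @return matrix with one row per time, one column per covariate.
#' @export
eval_path <- function(path, t) {
  stopifnot(inherits(path, "covariate_path"))
  if (any(t < 0) || any(t > max(path$breaks) + 1e-12)) {
    abort("`t` outside the path's domain [0, max(breaks)].")
  }
  idx <- findInterval(t, path$breaks, left.open = TRUE) + 1L
  idx <- pmin(idx, nrow(path$values))
  path$values[idx, , drop = FALSE]
}

#' @export
print.covariate_path <- function(x, ...) {
  cat(sprintf(
    "<covariate_path> %d segment(s), %d covariate(s), domain [0, %g]\n",
    length(x$breaks), ncol(x$values), max(x$breaks)
  ))
  invisible(x)
}
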