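# Independent brute-force oracles and small data builders shared by the
# tests. The oracles deliberately mirror the printed formulas as literal
# double loops over (subject, grid point); they never call the package's
# vectorised code paths.

# Direct double-loop evaluation of the censored discretised loss:
# (1/n) sum_i sum_j I(t_j <= y_i) [ e^h (t_j - t_{j-1}) - h delta_ij ].
# `h_mat[i, j]` indexes subject i at grid point j; t0 = 0.
oracle_censored_loss <- function(h_mat, y, delta, pts) {
  n <- length(y)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_along(pts)) {
      if (pts[j] <= y[i]) {
        width <- pts[j] - if (j == 1) 0 else pts[j - 1]
        dij <- delta[i] * as.numeric(pts[j] == y[i])
        total <- total + exp(h_mat[i, j]) * width - h_mat[i, j] * dij
      }
    }
  }
  total / n
}

# Uncensored analogue: sum over j >= 2 only, delta_ij = 1(t_j = y_i),
# constant term dropped.
oracle_uncensored_loss <- function(h_mat, y, pts) {
  n <- length(y)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_along(pts)) {
      if (j >= 2 && pts[j] <= y[i]) {
        width <- pts[j] - pts[j - 1]
        dij <- as.numeric(pts[j] == y[i])
        total <- total + exp(h_mat[i, j]) * width - h_mat[i, j] * dij
      }
    }
  }
  total / n
}

# Align a per-(subject, grid) matrix of h values with the rows of an
# expanded table (rows are subject-major, ordered by grid point).
h_for_table <- function(h_mat, table, ids = NULL) {
  pts <- attr(table, "grid")$points
  i_idx <- match(table$id, ids %||% sort(unique(table$id)))
  j_idx <- match(table$tstop, pts)
  h_mat[cbind(i_idx, j_idx)]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Simple censored long-format data with one constant-covariate interval per
# subject.
toy_censored <- function(y, delta, x = seq_along(y)) {
  tibble::tibble(
    id = seq_along(y), tstart = 0, tstop = y, event = delta, x1 = x
  )
}

# Covariate-free exponential survival data in long format (a constant
# covariate column keeps the expanded design non-empty).
exp_censored_data <- function(n, rate = 0.5, seed = 1) {
  set.seed(seed)
  toy_censored(rexp(n, rate), rep(1, n), x = rep(1, n))
}

# Random censored data with exact ties (times on a 0.1 lattice, each double
# computed through the same division) for oracle comparisons.
random_censored <- function(n, seed = 1) {
  set.seed(seed)
  y <- sample.int(40, n, replace = TRUE) / 10
  toy_censored(y, rbinom(n, 1, 0.7), x = rnorm(n))
}
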