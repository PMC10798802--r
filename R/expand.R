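#' Expand censored survival data to one row per (subject, grid point)
#'
#' Implements the counting-process data expansion used for Cox regression with
#' time-varying covariates: the time axis is partitioned by the unique sorted
#' observed times `t_1 < ... < t_m`, and subject `i` contributes one row for
#' every grid point `t_j <= y_i`, carrying the covariates in force at `t_j` and
#' an event indicator `delta_ij = delta_i * 1(t_j == y_i)`. The expanded rows
#' are exactly the evaluation points of the discretised full likelihood.
#'
#' @param data long-format (start-stop) data frame with columns `id`,
#'   `tstart`, `tstop`, `event` and at least one covariate column; each
#'   subject's intervals must tile `[0, y_i]` contiguously and `event = 1` may
#'   appear only on a subject's last interval.
#' @param grid optional [build_time_grid()] result; defaults to the grid of the
#'   subjects' own observed times. A validation fold is expanded on its own
#'   grid.
#' @return A tibble of class `expanded_table` with columns `id`, `tstart`,
#'   `tstop`, `delta`, `excluded` and the covariates, plus attributes `grid`,
#'   `mode` and `n_subjects`.
#' @seealso [expand_uncensored()], [censored_loss()]
#' @export
expand_censored <- function(data, grid = NULL) {
  data <- as_tibble(data)
  needed <- c("id", "tstart", "tstop", "event")
  if (!all(needed %in% names(data))) {
    abort(paste0(
      "censored data needs columns ",
      paste(setdiff(needed, names(data)), collapse = ", "), "."
    ))
  }
  covars <- setdiff(names(data), needed)
  if (length(covars) == 0) {
    abort("censored data needs at least one covariate column.")
  }
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0/1.")

  data <- dplyr::arrange(data, .data$id, .data$tstart)
  by_id <- split(seq_len(nrow(data)), data$id)

  subj <- purrr::map(by_id, function(rows) {
    tstart <- data$tstart[rows]
    tstop <- data$tstop[rows]
    ev <- data$event[rows]
    if (abs(tstart[1]) > 1e-12) {
      abort("each subject's first interval must start at 0.")
    }
    if (any(tstop <= tstart)) abort("intervals must have tstop > tstart.")
    k <- length(rows)
    if (k > 1 && any(abs(tstart[-1] - tstop[-k]) > 1e-12)) {
      abort("subject intervals must tile [0, y] without gaps or overlaps.")
    }
    if (any(ev[-k] == 1)) abort("`event` = 1 is allowed only on the last row.")
    list(y = tstop[k], delta = ev[k], rows = rows, tstop = tstop)
  })

  y <- purrr::map_dbl(subj, "y")
  if (is.null(grid)) grid <- build_time_grid(y, "censored")
  if (grid$mode != "censored") abort("`grid` must be a censored-mode grid.")
  pts <- grid$points
  tprev <- c(0, pts[-length(pts)])

  ids <- names(subj)
  out <- purrr::map2(subj, ids, function(s, id) {
    keep <- which(pts <= s$y + 1e-12)
    if (length(keep) == 0) return(NULL)
    tj <- pts[keep]
    if (max(tj) > max(s$tstop) + 1e-12) {
      abort("covariate path does not cover [0, y] for some subject.")
    }
    seg <- pmin(findInterval(tj, s$tstop, left.open = TRUE) + 1L, length(s$rows))
    tibble(
      id = rep(id, length(keep)),
      tstart = tprev[keep],
      tstop = tj,
      delta = as.numeric(s$delta * (abs(tj - s$y) < 1e-12)),
      excluded = FALSE
    ) |>
      dplyr::bind_cols(data[s$rows[seg], covars, drop = FALSE])
  })
  tab <- dplyr::bind_rows(out)
  # restore original id type when possible
  if (!is.character(data$id)) tab$id <- utils::type.convert(tab$id, as.is = TRUE)

  new_expanded_table(tab, grid, "censored", length(subj), covars)
}

#' Expand uncensored regression data for distribution-function estimation
#'
#' The same expansion as [expand_censored()] applied to an arbitrary continuous
#' response: the grid is the unique sorted responses, every subject's row at
#' `t_j == y_i` carries `delta = 1`, and the first interval (ending at the
#' smallest response `t_1`) is retained for bookkeeping but flagged `excluded`
#' -- it carries the fixed point mass `1/n` of the distribution estimate and
#' drops out of the loss. Covariates are constant within subject.
#'
#' @param data data frame with a response column `y` and covariate columns.
#' @param grid optional uncensored-mode [build_time_grid()].
#' @return An `expanded_table` tibble (see [expand_censored()]); `tstart` is
#'   `NA` on the excluded first rows, whose notional start is minus infinity.
#' @export
expand_uncensored <- function(data, grid = NULL) {
  data <- as_tibble(data)
  if (!"y" %in% names(data)) abort("uncensored data needs a `y` column.")
  covars <- setdiff(names(data), "y")
  if (length(covars) == 0) abort("uncensored data needs covariate columns.")
  if (!all(is.finite(data$y))) abort("`y` must be finite.")

  if (is.null(grid)) grid <- build_time_grid(data$y, "uncensored")
  if (grid$mode != "uncensored") abort("`grid` must be an uncensored-mode grid.")
  pts <- grid$points
  tprev <- c(NA_real_, pts[-length(pts)])

  n <- nrow(data)
  counts <- findInterval(data$y + 1e-12, pts)  # rows per subject
  j_idx <- sequence(counts)
  i_idx <- rep(seq_len(n), counts)
  tab <- tibble(
    id = i_idx,
    tstart = tprev[j_idx],
    tstop = pts[j_idx],
    delta = as.numeric(abs(pts[j_idx] - data$y[i_idx]) < 1e-12),
    excluded = j_idx == 1L
  ) |>
    dplyr::bind_cols(data[i_idx, covars, drop = FALSE])

  new_expanded_table(tab, grid, "uncensored", n, covars)
}

new_expanded_table <- function(tab, grid, mode, n_subjects, covariates) {
  structure(
    tab,
    grid = grid,
    mode = mode,
    n_subjects = n_subjects,
    covariates = covariates,
    class = c("expanded_table", class(tibble()))
  )
}

table_mode <- function(table) attr(table, "mode", exact = TRUE)
table_grid <- function(table) attr(table, "grid", exact = TRUE)
table_covariates <- function(table) attr(table, "covariates", exact = TRUE)
table_n <- function(table) attr(table, "n_subjects", exact = TRUE)
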