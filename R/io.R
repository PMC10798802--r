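#' Read and write the package's CSV formats
#'
#' Censored data use the standard counting-process (start-stop) layout:
#' columns `id`, `tstart`, `tstop`, `event` and covariates, one row per
#' covariate-constant interval; each subject's intervals must tile `[0, y]`
#' contiguously and `event = 1` may appear only on a subject's last row.
#' Uncensored data are plain `(y, covariates)` tables.
#'
#' @param path file path.
#' @return A validated tibble.
#' @export
read_censored_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  check_censored_long(data)
  data
}

#' @rdname read_censored_csv
#' @export
read_uncensored_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (!"y" %in% names(data)) abort("missing required column `y`.")
  if (ncol(data) < 2) abort("no covariate columns found.")
  if (!all(is.finite(data$y))) abort("`y` contains non-finite values.")
  data
}

#' @rdname read_censored_csv
#' @param data tibble in the corresponding layout.
#' @export
write_censored_csv <- function(data, path) {
  check_censored_long(data)
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' @rdname read_censored_csv
#' @export
write_uncensored_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

check_censored_long <- function(data) {
  needed <- c("id", "tstart", "tstop", "event")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (ncol(data) <= length(needed)) abort("no covariate columns found.")
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0/1.")
  data <- dplyr::arrange(as_tibble(data), .data$id, .data$tstart)
  for (rows in split(seq_len(nrow(data)), data$id)) {
    tstart <- data$tstart[rows]; tstop <- data$tstop[rows]
    k <- length(rows)
    if (abs(tstart[1]) > 1e-12) {
      abort("each subject's intervals must start at time 0.")
    }
    if (any(tstop <= tstart)) abort("found an interval with tstop <= tstart.")
    if (k > 1 && any(abs(tstart[-1] - tstop[-k]) > 1e-12)) {
      abort("subject intervals must tile [0, y] without gaps or overlaps.")
    }
    if (any(data$event[rows][-k] == 1)) {
      abort("`event` = 1 before a subject's last interval.")
    }
  }
  invisible(data)
}
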