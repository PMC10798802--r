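#' Training configuration for the hazard network
#'
#' Defaults follow the protocol used throughout the simulations: two hidden
#' layers of 64 nodes, batch size 100, initial learning rate 0.001 for the
#' Adam optimiser, and early stopping once the validation loss has failed to
#' improve for 10 consecutive epochs (best weights restored).
#'
#' @param nodes nodes per hidden layer.
#' @param learning_rate initial Adam learning rate.
#' @param batch_size minibatch size over expanded rows.
#' @param patience early-stopping patience, in epochs.
#' @param max_epochs hard cap on epochs.
#' @param seed integer seed controlling the split, the weight initialisation
#'   and the minibatch shuffling.
#' @param clamp bounds applied to `h` inside `exp()` in the loss.
#' @return A `training_config` list.
#' @export
training_config <- function(nodes = 64, learning_rate = 0.001,
                            batch_size = 100, patience = 10,
                            max_epochs = 500, seed = 1,
                            clamp = c(-30, 30)) {
  stopifnot(
    nodes >= 1, learning_rate > 0, batch_size >= 1, patience >= 1,
    max_epochs >= 1, length(clamp) == 2, clamp[1] < clamp[2]
  )
  structure(
    list(
      nodes = as.integer(nodes), learning_rate = learning_rate,
      batch_size = as.integer(batch_size), patience = as.integer(patience),
      max_epochs = as.integer(max_epochs), seed = as.integer(seed),
      clamp = clamp
    ),
    class = "training_config"
  )
}

#' Initialise an untrained log-hazard network
#'
#' A fully connected feed-forward net with two hidden ReLU layers, an identity
#' output (so `h` is unconstrained) and bias terms in every layer. Weights are
#' Glorot-uniform, biases zero.
#'
#' @param input_dim number of inputs: `t_prev`, `t_cur` and the covariates.
#' @param config a [training_config()].
#' @return A `dense_net` weight list.
#' @export
make_network <- function(input_dim, config = training_config()) {
  if (input_dim < 1) abort("`input_dim` must be at least 1.")
  set.seed(config$seed %% .Machine$integer.max)
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  k <- config$nodes
  structure(
    list(
      W1 = glorot(input_dim, k), b1 = rep(0, k),
      W2 = glorot(k, k), b2 = rep(0, k),
      w3 = as.numeric(glorot(k, 1)), b3 = 0
    ),
    class = "dense_net"
  )
}

#' @export
print.dense_net <- function(x, ...) {
  np <- length(x$W1) + length(x$b1) + length(x$W2) + length(x$b2) +
    length(x$w3) + 1
  cat(sprintf(
    "<dense_net> %d-%d-%d-1, %d parameters\n",
    nrow(x$W1), ncol(x$W1), ncol(x$W2), np
  ))
  invisible(x)
}

# Design matrix, interval widths and event indicators from the loss-relevant
# (non-excluded) rows of an expanded table.
table_matrices <- function(table) {
  keep <- !table$excluded
  covars <- table_covariates(table)
  X <- cbind(
    tprev = table$tstart[keep],
    tcur = table$tstop[keep],
    as.matrix(table[keep, covars, drop = FALSE])
  )
  list(
    X = X,
    width = table$tstop[keep] - table$tstart[keep],
    delta = table$delta[keep]
  )
}

standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

apply_std <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Train the hazard network with early stopping
#'
#' Minimises the discretised likelihood loss of the table's mode
#' ([censored_loss()] or [uncensored_loss()]) by minibatch Adam over expanded
#' rows. The validation loss is evaluated on the validation subjects expanded
#' on their own observed-time grid; training stops when it has not improved
#' for `patience` consecutive epochs and the best-validation weights are
#' restored. Inputs (`t_prev`, `t_cur`, covariates) are standardised by
#' training-set mean and SD; the transform is stored with the model.
#'
#' @param train,val `expanded_table`s of the same mode and covariates.
#' @param config a [training_config()].
#' @return A `hazard_fit` holding one network; see [fit_hazard()] for the
#'   swap-and-average estimator.
#' @export
train_early_stopping <- function(train, val, config = training_config()) {
  if (!inherits(train, "expanded_table") || !inherits(val, "expanded_table")) {
    abort("`train` and `val` must be expanded_tables.")
  }
  if (!identical(table_mode(train), table_mode(val)) ||
      !identical(table_covariates(train), table_covariates(val))) {
    abort("`train` and `val` must share mode and covariates.")
  }
  if (nrow(train) == 0 || nrow(val) == 0) abort("empty expanded table.")

  tr <- table_matrices(train)
  va <- table_matrices(val)
  std <- standardizer(tr$X)

  net <- make_network(ncol(tr$X), config)
  res <- nn_train_cpp(
    apply_std(tr$X, std), tr$width, tr$delta,
    apply_std(va$X, std), va$width, va$delta,
    unclass(net), 0L, config$learning_rate, config$batch_size,
    config$patience, config$max_epochs, config$clamp[1], config$clamp[2],
    (config$seed + 7L) %% .Machine$integer.max
  )

  history <- tibble(
    epoch = seq_along(res$train_loss),
    train_loss = res$train_loss / table_n(train),
    val_loss = res$val_loss / table_n(val)
  )
  new_hazard_fit(
    nets = list(res[c("W1", "b1", "W2", "b2", "w3", "b3")]),
    std = std, grid = table_grid(train), mode = table_mode(train),
    covariates = table_covariates(train), n_train = table_n(train),
    config = config,
    history = list(history),
    best_epoch = res$best_epoch, stopped_epoch = res$stopped_epoch,
    best_val = res$best_val / table_n(val)
  )
}

new_hazard_fit <- function(nets, std, grid, mode, covariates, n_train, config,
                           history, best_epoch, stopped_epoch, best_val) {
  structure(
    list(
      nets = nets, std = std, grid = grid, mode = mode,
      covariates = covariates, n_train = n_train, config = config,
      history = history, best_epoch = best_epoch,
      stopped_epoch = stopped_epoch, best_val = best_val
    ),
    class = "hazard_fit"
  )
}

#' Fit the log-hazard network by swap-and-average
#'
#' The sample is split 1:1 at random into two halves. The network is trained
#' on the first half with the second as the early-stopping validation set,
#' then refitted with the roles swapped; the final estimator averages the two
#' networks' log-hazard outputs pointwise. Each half is expanded on its own
#' observed-time grid during training; the returned fit reconstructs curves on
#' the pooled grid of all observed times, so the whole sample informs the
#' integration grid and the `1/n` mass.
#'
#' @param data censored long-format data (`id`, `tstart`, `tstop`, `event`,
#'   covariates) or an uncensored data frame (`y`, covariates).
#' @param mode `"censored"` or `"uncensored"`.
#' @param config a [training_config()].
#' @param swap_average set `FALSE` to keep a single early-stopped fit (the
#'   first half trains, the second validates).
#' @return A `hazard_fit`.
#' @export
fit_hazard <- function(data, mode = c("censored", "uncensored"),
                       config = training_config(), swap_average = TRUE) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  if (mode == "censored") {
    ids <- unique(data$id)
    subset_fun <- function(keep) data[data$id %in% keep, , drop = FALSE]
    expand_fun <- expand_censored
    all_times <- dplyr::summarise(
      dplyr::group_by(data, .data$id), y = max(.data$tstop)
    )$y
  } else {
    ids <- seq_len(nrow(data))
    subset_fun <- function(keep) data[keep, , drop = FALSE]
    expand_fun <- expand_uncensored
    all_times <- data$y
  }
  if (length(ids) < 4) abort("need at least 4 subjects to split 1:1.")

  set.seed(config$seed %% .Machine$integer.max)
  shuffled <- sample(ids)
  half1 <- shuffled[seq_len(floor(length(ids) / 2))]
  half2 <- setdiff(shuffled, half1)
  t1 <- expand_fun(subset_fun(half1))
  t2 <- expand_fun(subset_fun(half2))

  cfg_a <- config
  cfg_a$seed <- (config$seed + 101L) %% .Machine$integer.max
  fit_a <- train_early_stopping(t1, t2, cfg_a)
  if (!swap_average) {
    fit_a$n_train <- table_n(t1)
    return(fit_a)
  }
  cfg_b <- config
  cfg_b$seed <- (config$seed + 202L) %% .Machine$integer.max
  fit_b <- train_early_stopping(t2, t1, cfg_b)

  # Averaging is done on the h (log-hazard) scale -- the networks' outputs.
  pooled <- build_time_grid(all_times, mode)
  new_hazard_fit(
    nets = c(fit_a$nets, fit_b$nets),
    std = list(fit_a$std, fit_b$std),
    grid = pooled, mode = mode,
    covariates = fit_a$covariates, n_train = length(ids), config = config,
    history = c(fit_a$history, fit_b$history),
    best_epoch = c(fit_a$best_epoch, fit_b$best_epoch),
    stopped_epoch = c(fit_a$stopped_epoch, fit_b$stopped_epoch),
    best_val = c(fit_a$best_val, fit_b$best_val)
  )
}

#' Evaluate the fitted log conditional hazard
#'
#' Returns `h(t_prev, t_cur, x)`, averaging the swapped fits' outputs when the
#' model was fitted by swap-and-average.
#'
#' @param fit a `hazard_fit`.
#' @param tprev,tcur interval endpoints, recycled against `X`.
#' @param X covariate matrix (one row per prediction) in training column
#'   order, or with matching column names.
#' @return Numeric vector of log-hazard values.
#' @export
predict_h <- function(fit, tprev, tcur, X) {
  stopifnot(inherits(fit, "hazard_fit"))
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && all(fit$covariates %in% colnames(X))) {
    X <- X[, fit$covariates, drop = FALSE]
  }
  if (ncol(X) != length(fit$covariates)) {
    abort("`X` must supply the model's covariates.")
  }
  n <- max(length(tprev), length(tcur), nrow(X))
  Xm <- cbind(
    tprev = rep_len(tprev, n), tcur = rep_len(tcur, n),
    X[rep_len(seq_len(nrow(X)), n), , drop = FALSE]
  )
  stds <- if (inherits(fit$std, "list") && !is.null(fit$std$center)) {
    rep(list(fit$std), length(fit$nets))
  } else {
    fit$std
  }
  hs <- purrr::map2(fit$nets, stds, function(net, std) {
    nn_forward_cpp(net, apply_std(Xm, std))
  })
  Reduce(`+`, hs) / length(hs)
}

#' Exhaustive hyperparameter grid search
#'
#' Fits one early-stopped network per combination of nodes, learning rate and
#' batch size on a fixed seeded split and returns the configuration with the
#' lowest best validation loss; ties go to the earliest grid entry. The
#' default grid is nodes {64, 128, 256} x learning rate
#' {0.1, 0.01, 0.001, 0.0001} x batch {64, 128, 256} (36 combinations).
#'
#' @param data as in [fit_hazard()].
#' @param mode `"censored"` or `"uncensored"`.
#' @param grid named list with elements `nodes`, `learning_rate`,
#'   `batch_size`.
#' @param config base [training_config()] supplying the remaining settings.
#' @return The winning `training_config`, with the search table in attribute
#'   `"search"`.
#' @export
tune_hyperparameters <- function(data, mode = c("censored", "uncensored"),
                                 grid = list(
                                   nodes = c(64, 128, 256),
                                   learning_rate = c(0.1, 0.01, 0.001, 1e-4),
                                   batch_size = c(64, 128, 256)
                                 ),
                                 config = training_config()) {
  mode <- match.arg(mode)
  if (any(lengths(grid) == 0)) abort("empty hyperparameter grid.")
  combos <- expand.grid(
    nodes = grid$nodes, learning_rate = grid$learning_rate,
    batch_size = grid$batch_size, KEEP.OUT.ATTRS = FALSE
  )
  losses <- purrr::map_dbl(seq_len(nrow(combos)), function(k) {
    cfg <- training_config(
      nodes = combos$nodes[k], learning_rate = combos$learning_rate[k],
      batch_size = combos$batch_size[k], patience = config$patience,
      max_epochs = config$max_epochs, seed = config$seed,
      clamp = config$clamp
    )
    fit_hazard(data, mode, cfg, swap_average = FALSE)$best_val
  })
  best <- which.min(losses)
  out <- training_config(
    nodes = combos$nodes[best], learning_rate = combos$learning_rate[best],
    batch_size = combos$batch_size[best], patience = config$patience,
    max_epochs = config$max_epochs, seed = config$seed, clamp = config$clamp
  )
  attr(out, "search") <- dplyr::bind_cols(as_tibble(combos), val_loss = losses)
  out
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf(
    "<hazard_fit> %s mode, %d network(s), n_train = %d, grid of %d points\n",
    x$mode, length(x$nets), x$n_train, length(x$grid$points)
  ))
  cat(sprintf(
    "  stopped at epoch(s) %s, best validation loss %s\n",
    paste(x$stopped_epoch, collapse = ", "),
    paste(signif(x$best_val, 5), collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.hazard_fit <- function(x, ...) {
  purrr::imap(x$history, function(hist, k) {
    dplyr::mutate(hist, network = k, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
      names_to = "set", values_to = "loss"
    ) |>
    dplyr::mutate(set = sub("_loss$", "", .data$set))
}

#' @export
glance.hazard_fit <- function(x, ...) {
  tibble(
    mode = x$mode, n_train = x$n_train, n_networks = length(x$nets),
    grid_size = length(x$grid$points),
    best_val_loss = mean(x$best_val),
    stopped_epoch = max(x$stopped_epoch)
  )
}

#' @export
autoplot.hazard_fit <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(
      x = .data$epoch, y = .data$loss, colour = .data$set,
      linetype = factor(.data$network)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(linetype = "network", y = "loss (per subject)")
}

#' Serialise / restore a fitted model
#'
#' The fit (architecture, weights, standardisation constants, grid and
#' configuration) is written as a single self-describing file and reloads
#' deterministically.
#'
#' @param fit a `hazard_fit`.
#' @param path file path.
#' @export
write_hazard_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hazard_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_hazard_fit
#' @export
read_hazard_fit <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "hazard_fit")) abort("`path` does not hold a hazard_fit.")
  fit
}
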