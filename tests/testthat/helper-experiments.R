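# The replicated simulation experiments are expensive, and several acceptance
# checks read different columns of the same run; compute each once per test
# session and cache.
.exp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .exp_cache)) {
    assign(key, force(expr), envir = .exp_cache)
  }
  get(key, envir = .exp_cache)
}

setup1_runs <- function() {
  cached("setup1", run_uncensored_experiment(
    "indep", n = 1000, c = 0.5, n_test = 500, reps = 5, seed = 1
  ))
}

setup2_runs <- function() {
  cached("setup2", run_uncensored_experiment(
    "corr", n = 1000, c = 0.5, n_test = 500, reps = 5, seed = 1
  ))
}

kernel_runs_1d <- function() {
  cached("kernel1", run_kernel_experiment(dims = 1, n = 1000, reps = 10, seed = 1))
}

kernel_runs_2d <- function() {
  cached("kernel2", run_kernel_experiment(dims = 2, n = 1000, reps = 5, seed = 1))
}
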