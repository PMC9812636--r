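#' Sweep the number of CSSD filters
#'
#' Refits and evaluates the whole pipeline for each candidate `J` on one
#' shared stratified train/test split, so rows differ only in `J`. A `J`
#' that exceeds the effective covariance rank is recorded as a per-row
#' error and the sweep continues.
#'
#' @param data a labelled [epoched_recording()].
#' @param config a [pipeline_config()]; its `J` is overridden per row.
#' @param J_values integer vector of filter counts to try.
#' @param train_fraction training fraction of the shared split.
#' @param seed split seed (default `config$seed`).
#' @return A tibble with one row per `J`: `J`, `accuracy`, `n_train`,
#'   `n_test`, `split_fingerprint`, `error` (`NA` when the fit
#'   succeeded); class `cssdelm_sweep_j`.
#' @examples
#' rec <- simulate_recording(synthetic_config(n_trials_per_class = 20, seed = 2))
#' sweep_eigenvalues(rec, pipeline_config(channels_m = 10, ar_order = 8),
#'                   J_values = c(2, 4))
#' @export
sweep_eigenvalues <- function(data, config = pipeline_config(),
                              J_values = c(3L, 5L, 10L),
                              train_fraction = 0.5, seed = NULL) {
  seed <- seed %||% config$seed
  split <- split_train_test(data, fraction = train_fraction, seed = seed)
  split_fp <- rlang::hash(split$train_idx)
  rows <- lapply(as.integer(J_values), function(J) {
    cfg <- config
    cfg$J <- J
    res <- tryCatch({
      fit <- fit_pipeline(split$train, cfg)
      ev <- evaluate(fit, split$test)
      list(acc = ev$accuracy, err = NA_character_)
    }, error = function(e) list(acc = NA_real_, err = conditionMessage(e)))
    tibble(J = J, accuracy = res$acc,
           n_train = n_trials(split$train), n_test = n_trials(split$test),
           split_fingerprint = split_fp, error = res$err)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cssdelm_sweep_j", class(out))
  out
}

#' Sweep the training fraction
#'
#' For each training fraction, draws `n_seeds` stratified splits, refits
#' the pipeline on each training part (channel selection included — no
#' information crosses a split) and reports mean and standard deviation of
#' test accuracy. Infeasible fractions (no test data, or fewer than two
#' training trials per class) are recorded as per-row errors.
#'
#' @param data a labelled [epoched_recording()].
#' @param config a [pipeline_config()].
#' @param fractions training fractions to try.
#' @param n_seeds splits per fraction.
#' @return A tibble with one row per fraction: `fraction`,
#'   `mean_accuracy`, `sd_accuracy`, `n_seeds`, `error`; class
#'   `cssdelm_sweep_fraction`.
#' @export
sweep_train_fraction <- function(data, config = pipeline_config(),
                                 fractions = c(0.1, 0.25, 0.5),
                                 n_seeds = 5L) {
  rows <- lapply(fractions, function(fr) {
    accs <- tryCatch({
      vapply(seq_len(n_seeds), function(s) {
        split <- split_train_test(data, fraction = fr,
                                  seed = config$seed + s - 1L)
        evaluate(fit_pipeline(split$train, config), split$test)$accuracy
      }, numeric(1))
    }, error = function(e) e)
    if (inherits(accs, "error")) {
      tibble(fraction = fr, mean_accuracy = NA_real_, sd_accuracy = NA_real_,
             n_seeds = as.integer(n_seeds), error = conditionMessage(accs))
    } else {
      tibble(fraction = fr, mean_accuracy = mean(accs),
             sd_accuracy = stats::sd(accs),
             n_seeds = as.integer(n_seeds), error = NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cssdelm_sweep_fraction", class(out))
  out
}
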