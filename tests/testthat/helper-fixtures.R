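# Small cohorts used throughout the unit tests; full-size cohorts are built
# only in test-acceptance.R.

small_config <- function(...) {
  args <- list(...)
  if (is.null(args$shared_peaks)) {
    pk <- default_serum_peaks()
    args$shared_peaks <- pk[pk$center >= 520 & pk$center <= 1280, ]
  }
  do.call(cohort_config, utils::modifyList(
    list(n_target = 10, n_control = 8, replicates_per_subject = 2,
         axis_start = 500, axis_stop = 1300, axis_step = 4),
    args
  ))
}

# deterministic structural cohort: no randomness at all
clean_config <- function(...) {
  small_config(subject_sd = 0, replicate_sd = 0, noise_sd = 0, ...)
}

# X with one perfectly informative channel and pure-noise remainder;
# balanced classes, one subject per spectrum pair
separable_fixture <- function(n_per_class = 12, p_noise = 6, seed = 42) {
  withr::with_seed(seed, {
    y <- rep(c(1, 0), each = n_per_class)
    informative <- ifelse(y == 1, 3, -3)
    X <- cbind(informative,
               matrix(rnorm(2 * n_per_class * p_noise, sd = 0.5), ncol = p_noise))
    colnames(X) <- as.character(seq_len(ncol(X)))
    list(X = X, y = y,
         subjects = paste0("s", rep(seq_len(n_per_class), 2), rep(c("t", "c"), each = n_per_class)))
  })
}
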