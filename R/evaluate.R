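#' Split subjects into training and test sets
#'
#' Per class, `floor(train_frac * n_subjects)` subjects are drawn uniformly
#' at random into the training set; the rest form the test set. All of a
#' subject's replicate spectra follow its assignment. Deterministic given
#' `seed`.
#'
#' @param ds spectra tibble.
#' @param train_frac training fraction of subjects per class (default 0.8).
#' @param seed integer seed.
#' @return object of class `split_plan`: character vectors
#'   `train_subjects`, `test_subjects`, plus `seed`.
#' @export
split_subjects <- function(ds, train_frac = 0.8, seed = 1L) {
  validate_spectra(ds)
  subj <- dplyr::distinct(spectra_meta(ds), .data$subject_id, .data$group)
  counts <- table(subj$group)
  if (any(counts < 2)) abort("every class needs at least 2 subjects to split")
  withr::with_seed(seed, {
    train <- subj |>
      dplyr::group_by(.data$group) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::filter(dplyr::row_number() <= floor(train_frac * dplyr::n())) |>
      dplyr::ungroup()
  })
  structure(
    list(train_subjects = sort(train$subject_id),
         test_subjects = sort(setdiff(subj$subject_id, train$subject_id)),
         seed = seed),
    class = "split_plan"
  )
}

#' Confusion-matrix metrics for a two-class problem
#'
#' Sensitivity is recall on the Target (patient) class, specificity recall
#' on the Control class, accuracy the overall fraction correct.
#'
#' @param truth,predicted class vectors with values Target/Control; `truth`
#'   must contain both classes.
#' @return one-row tibble with `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) abort("length mismatch")
  if (length(unique(truth)) < 2) abort("truth must contain both classes")
  is_t <- truth == "Target"
  tibble(
    sensitivity = mean(predicted[is_t] == "Target"),
    specificity = mean(predicted[!is_t] == "Control"),
    accuracy = mean(predicted == truth)
  )
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen Target score exceeds a randomly
#' chosen Control score, with ties counting one half — computed exactly
#' over all cross-pairs via midranks.
#'
#' @param truth class vector (Target/Control), both classes present.
#' @param score numeric classifier score (higher = more Target-like).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(truth, score) {
  t <- as.character(truth) == "Target"
  n_t <- sum(t); n_c <- sum(!t)
  if (n_t == 0 || n_c == 0) abort("truth must contain both classes")
  r <- rank(score)
  (sum(r[t]) - n_t * (n_t + 1) / 2) / (n_t * n_c)
}

eval_fold <- function(truth, pred, subject_id, subject_vote = FALSE) {
  if (subject_vote) {
    agg <- tibble(subject_id = subject_id, truth = as.character(truth),
                  score = pred$score) |>
      dplyr::group_by(.data$subject_id, .data$truth) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop")
    truth <- agg$truth
    pred <- tibble(score = agg$score,
                   label = ifelse(agg$score >= 0.5, "Target", "Control"))
  }
  dplyr::bind_cols(
    confusion_metrics(truth, pred$label),
    tibble(auc = roc_auc(truth, pred$score))
  )
}

#' Run the repeated-split validation protocol
#'
#' The full evaluation scheme: for each of `n_iterations` iterations the
#' subjects of each class are split 80/20 into training and test sets; the
#' component count is selected on the training set alone by subject-grouped
#' k-fold cross-validation; a PLS-DA model is fitted on the training
#' spectra and scored on both subsets; sensitivity, specificity, accuracy
#' and ROC AUC are recorded per subset. Test subjects never touch any
#' fitting or selection step. All randomness derives from
#' `base_seed + iteration`.
#'
#' @param ds preprocessed spectra tibble.
#' @param n_iterations number of repeated splits (default 30).
#' @param k folds for component selection (default 7).
#' @param grid candidate component counts (`NULL` = `1:15`, rank-capped).
#' @param train_frac per-class training fraction of subjects.
#' @param base_seed integer; iteration `i` uses seed `base_seed + i`.
#' @param subject_vote if `TRUE`, metrics are computed per subject using
#'   the mean replicate score (majority-style vote); the default counts
#'   every spectrum separately.
#' @return object of class `sers_protocol`: `per_iteration` tibble
#'   (iteration, subsample, metrics, chosen_A), `aggregate` (mean/min/max
#'   per metric per subsample), `mean_vip` (VIP profile averaged over
#'   iterations), `splits` (per-iteration `split_plan`s), `cv_folds`
#'   (per-iteration subject-to-fold tables), and the settings used.
#' @export
run_protocol <- function(ds, n_iterations = 30, k = 7, grid = NULL,
                         train_frac = 0.8, base_seed = 1L,
                         subject_vote = FALSE) {
  validate_spectra(ds)
  X <- spectra_matrix(ds)
  y <- class_code(ds$group)
  axis <- spectra_axis(ds)
  rows <- list(); splits <- list(); cv_folds <- list()
  vip_sum <- numeric(ncol(X))
  for (i in seq_len(n_iterations)) {
    seed_i <- base_seed + i
    plan <- split_subjects(ds, train_frac, seed = seed_i)
    tr <- ds$subject_id %in% plan$train_subjects
    if (length(unique(y[!tr])) < 2) {
      abort(sprintf("iteration %d: test set lacks a class", i))
    }
    sel <- select_components(X[tr, , drop = FALSE], y[tr], ds$subject_id[tr],
                             k = k, grid = grid, seed = seed_i + 10000L)
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], sel$chosen_A)
    vip_sum <- vip_sum + vip(fit)$vip
    for (sub in c("train", "test")) {
      idx <- if (sub == "train") tr else !tr
      pred <- predict(fit, X[idx, , drop = FALSE])
      m <- eval_fold(ds$group[idx], pred, ds$subject_id[idx], subject_vote)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(iteration = i, subsample = sub, chosen_A = sel$chosen_A), m
      )
    }
    splits[[i]] <- plan
    cv_folds[[i]] <- sel$folds
  }
  per_iteration <- dplyr::bind_rows(rows)
  aggregate <- per_iteration |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "accuracy", "auc"),
                        names_to = "metric") |>
    dplyr::group_by(.data$subsample, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), min = min(.data$value),
                     max = max(.data$value), .groups = "drop")
  mv <- tibble(wavenumber = axis, vip = vip_sum / n_iterations)
  class(mv) <- c("vip_profile", class(mv))
  structure(
    list(per_iteration = per_iteration, aggregate = aggregate,
         mean_vip = mv, splits = splits, cv_folds = cv_folds,
         settings = list(n_iterations = n_iterations, k = k,
                         train_frac = train_frac, base_seed = base_seed,
                         subject_vote = subject_vote)),
    class = "sers_protocol"
  )
}

#' @export
print.sers_protocol <- function(x, ...) {
  cat(sprintf("Repeated-split PLS-DA protocol: %d iterations\n",
              x$settings$n_iterations))
  print(table3_render(x))
  invisible(x)
}

#' Per-iteration metrics of a protocol run
#' @param x a `sers_protocol`.
#' @param ... unused.
#' @return the per-iteration tibble.
#' @exportS3Method generics::tidy
tidy.sers_protocol <- function(x, ...) x$per_iteration

#' One-row summary of a protocol run
#' @param x a `sers_protocol`.
#' @param ... unused.
#' @return one-row tibble of mean train/test metrics plus iteration count.
#' @exportS3Method generics::glance
glance.sers_protocol <- function(x, ...) {
  wide <- x$aggregate |>
    dplyr::mutate(key = paste(.data$subsample, .data$metric, sep = "_")) |>
    dplyr::select("key", "mean") |>
    tidyr::pivot_wider(names_from = "key", values_from = "mean")
  dplyr::bind_cols(wide, tibble(n_iterations = x$settings$n_iterations))
}

# accuracy-optimal threshold rule on a single feature, chosen on the
# training values only; returns a predictor function
best_threshold_rule <- function(feature, y) {
  cand <- sort(unique(feature))
  cuts <- c(-Inf, (cand[-1] + cand[-length(cand)]) / 2, Inf)
  best <- list(acc = -1, cut = 0, dir = 1L)
  for (cut in cuts) {
    for (dir in c(1L, -1L)) {
      pred <- if (dir == 1L) feature >= cut else feature < cut
      acc <- mean(pred == (y == 1))
      if (acc > best$acc) best <- list(acc = acc, cut = cut, dir = dir)
    }
  }
  function(x) {
    hit <- if (best$dir == 1L) x >= best$cut else x < best$cut
    ifelse(hit, "Target", "Control")
  }
}

#' Accuracy of a single spectral band under the repeated-split protocol
#'
#' The comparator to the full-spectrum model: the feature is the mean
#' preprocessed intensity over `[center - halfwidth, center + halfwidth]`,
#' classified by the accuracy-optimal threshold (direction and cutoff
#' chosen on the training subjects only) under the same repeated 80/20
#' subject-level splits as [run_protocol()].
#'
#' @param ds preprocessed spectra tibble.
#' @param center band center (cm^-1); must lie on the axis range.
#' @param halfwidth band half-width (cm^-1); the band must cover at least
#'   one channel.
#' @param n_iterations,train_frac,base_seed as in [run_protocol()].
#' @return mean test accuracy across iterations, with the per-iteration
#'   accuracies attached as attribute `"per_iteration"`.
#' @export
single_band_accuracy <- function(ds, center, halfwidth, n_iterations = 30,
                                 train_frac = 0.8, base_seed = 1L) {
  validate_spectra(ds)
  axis <- spectra_axis(ds)
  if (center < min(axis) || center > max(axis)) {
    abort("band center lies outside the wavenumber axis")
  }
  chan <- which(axis >= center - halfwidth & axis <= center + halfwidth)
  if (length(chan) == 0) abort("band covers no channels")
  feature <- rowMeans(spectra_matrix(ds)[, chan, drop = FALSE])
  y <- class_code(ds$group)
  acc <- vapply(seq_len(n_iterations), function(i) {
    plan <- split_subjects(ds, train_frac, seed = base_seed + i)
    tr <- ds$subject_id %in% plan$train_subjects
    rule <- best_threshold_rule(feature[tr], y[tr])
    mean(rule(feature[!tr]) == as.character(ds$group[!tr]))
  }, numeric(1))
  structure(mean(acc), per_iteration = acc)
}

#' Extract discriminative bands from a VIP profile
#'
#' Contiguous runs of channels with VIP at or above `threshold` become
#' intervals, each annotated with the position and height of its VIP
#' maximum. Intervals are listed in axis order; the print method ranks
#' them by peak height.
#'
#' @param profile a `vip_profile` tibble (`wavenumber`, `vip`).
#' @param threshold VIP cutoff (>= 0); the conventional default 1 marks
#'   greater-than-average importance.
#' @return tibble of class `band_report` with columns `low`, `high`,
#'   `peak_position`, `peak_vip`, sorted by position; the threshold is
#'   attached as an attribute.
#' @export
band_report <- function(profile, threshold = 1) {
  if (threshold < 0) abort("threshold must be >= 0")
  v <- profile$vip
  wn <- profile$wavenumber
  above <- v >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- purrr::map(keep, function(j) {
    i <- starts[j]:ends[j]
    pk <- i[which.max(v[i])]
    tibble(low = wn[i[1]], high = wn[i[length(i)]],
           peak_position = wn[pk], peak_vip = v[pk])
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(low = numeric(), high = numeric(),
           peak_position = numeric(), peak_vip = numeric())
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("band_report", class(out))
  out
}

#' @export
print.band_report <- function(x, ...) {
  cat(sprintf("Discriminative bands (VIP >= %g), ranked by peak height:\n",
              attr(x, "threshold")))
  ord <- order(-x$peak_vip)
  df <- as.data.frame(x)[ord, , drop = FALSE]
  if (nrow(df) == 0) cat("  (none)\n") else print(df, row.names = FALSE)
  invisible(x)
}
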