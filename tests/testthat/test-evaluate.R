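test_that("split_subjects takes floor(80%) of each class and partitions subjects", {
  ds <- generate_cohort(cohort_config(seed = 2))
  plan <- split_subjects(ds, 0.8, seed = 7)
  meta <- dplyr::distinct(spectra_meta(ds), subject_id, group)
  grp <- function(ids) table(meta$group[match(ids, meta$subject_id)])
  expect_equal(unname(c(grp(plan$train_subjects))), c(38, 24))
  expect_equal(unname(c(grp(plan$test_subjects))), c(10, 6))
  expect_length(intersect(plan$train_subjects, plan$test_subjects), 0)
  expect_setequal(c(plan$train_subjects, plan$test_subjects), meta$subject_id)
  expect_identical(plan, split_subjects(ds, 0.8, seed = 7))
  expect_false(identical(plan$train_subjects,
                         split_subjects(ds, 0.8, seed = 8)$train_subjects))

  one <- dplyr::filter(ds, subject_id %in% c("T01", "C01", "C02"))
  expect_error(split_subjects(one), "2 subjects")
})

test_that("confusion metrics match hand-computed 2x2 tables", {
  perfect <- c(rep("Target", 3), rep("Control", 2))
  expect_equal(as.numeric(confusion_metrics(perfect, perfect)), c(1, 1, 1))

  truth <- rep(c("Target", "Control"), each = 5)
  pred <- c("Target", "Target", "Target", "Target", "Control",  # 1 missed Target
            "Target", "Target", rep("Control", 3))              # 2 false Targets
  m <- confusion_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$accuracy, 0.7)

  expect_error(confusion_metrics(rep("Target", 4), rep("Target", 4)), "both classes")
})

test_that("roc_auc is the exact Mann-Whitney statistic", {
  expect_equal(roc_auc(c("Target", "Target", "Control", "Control"),
                       c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(roc_auc(rep(c("Target", "Control"), 5), rep(0.3, 10)), 0.5)
  sep <- c(rep(1, 4), rep(0, 4))
  expect_equal(roc_auc(ifelse(sep == 1, "Target", "Control"),
                       sep + c(1:4, 1:4) / 10), 1.0)
  expect_error(roc_auc(rep("Target", 3), 1:3), "both classes")
})

test_that("roc_auc agrees with an independent ROC implementation under ties", {
  skip_if_not_installed("pROC")
  withr::local_seed(14)
  for (i in 1:5) {
    truth <- ifelse(rbinom(40, 1, 0.5) == 1, "Target", "Control")
    if (length(unique(truth)) < 2) next
    score <- round(rnorm(40), 1)  # rounding forces ties
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = score, levels = c("Control", "Target"),
      direction = "<", quiet = TRUE
    )))
    expect_equal(roc_auc(truth, score), ref, tolerance = 1e-12)
  }
})

test_that("the repeated-split protocol has the declared structure and is leakage-free", {
  ds <- generate_cohort(small_config(seed = 21))
  pp <- preprocess_dataset(ds)
  res <- run_protocol(pp, n_iterations = 5, k = 4, base_seed = 3)

  expect_equal(nrow(res$per_iteration), 5 * 2)
  expect_true(all(res$per_iteration$subsample %in% c("train", "test")))
  metrics <- res$per_iteration[c("sensitivity", "specificity", "accuracy", "auc")]
  expect_true(all(metrics >= 0 & metrics <= 1))

  # aggregation correctness: recomputing mean/min/max reproduces the block
  recomputed <- res$per_iteration |>
    tidyr::pivot_longer(c(sensitivity, specificity, accuracy, auc),
                        names_to = "metric") |>
    dplyr::group_by(subsample, metric) |>
    dplyr::summarise(mean = mean(value), min = min(value), max = max(value),
                     .groups = "drop")
  expect_equal(res$aggregate, recomputed)

  # subject integrity: no subject straddles a split or a CV fold
  meta <- dplyr::distinct(spectra_meta(ds), subject_id, group)
  for (i in seq_along(res$splits)) {
    plan <- res$splits[[i]]
    expect_length(intersect(plan$train_subjects, plan$test_subjects), 0)
    expect_setequal(c(plan$train_subjects, plan$test_subjects), meta$subject_id)
    folds <- res$cv_folds[[i]]
    expect_setequal(folds$subject_id, plan$train_subjects)
    expect_equal(anyDuplicated(folds$subject_id), 0L)
  }

  # determinism: same seed, identical outputs
  res2 <- run_protocol(pp, n_iterations = 5, k = 4, base_seed = 3)
  expect_identical(res$per_iteration, res2$per_iteration)
  expect_identical(res$mean_vip, res2$mean_vip)
})

test_that("permutation of class labels destroys test performance but not train overfit", {
  ds <- generate_cohort(small_config(n_target = 12, n_control = 12, seed = 31))
  pp <- preprocess_dataset(ds)
  meta <- dplyr::distinct(spectra_meta(pp), subject_id, group)
  withr::with_seed(8, {
    shuffled <- tibble::tibble(subject_id = meta$subject_id,
                               group = sample(as.character(meta$group)))
  })
  perm <- pp
  perm$group <- factor(shuffled$group[match(perm$subject_id, shuffled$subject_id)],
                       levels = c("Target", "Control"))
  res <- run_protocol(perm, n_iterations = 10, k = 4, base_seed = 5)
  agg <- glance(res)
  expect_lt(abs(agg$test_auc - 0.5), 0.2)
  expect_gt(agg$train_accuracy, agg$test_accuracy)
})

test_that("test AUC never systematically decreases as the effect grows", {
  aucs <- vapply(c(1, 1.5, 2), function(er) {
    cfg <- small_config(effect_ratio = er, seed = 77)
    pp <- preprocess_dataset(generate_cohort(cfg))
    glance(run_protocol(pp, n_iterations = 10, k = 4, base_seed = 7))$test_auc
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.05))
  expect_gt(aucs[3], aucs[1])
})

test_that("single-band accuracy separates planted from off-effect bands", {
  cfg <- small_config(effect_ratio = 2.5, seed = 41,
                      effect_bands = list(c(900, 14)),
                      shared_peaks = dplyr::bind_rows(
                        peak_spec(600, 16, 0.5), peak_spec(700, 16, 0.5),
                        peak_spec(800, 16, 0.5), peak_spec(900, 16, 0.2),
                        peak_spec(1000, 16, 0.5), peak_spec(1100, 16, 0.5)
                      ))
  pp <- preprocess_dataset(generate_cohort(cfg))
  on_band <- single_band_accuracy(pp, 900, 10, n_iterations = 10, base_seed = 2)
  off_band <- single_band_accuracy(pp, 700, 10, n_iterations = 10, base_seed = 2)
  expect_gt(on_band, off_band)
  expect_length(attr(on_band, "per_iteration"), 10)

  expect_error(single_band_accuracy(pp, 2000, 10), "outside")
  expect_error(single_band_accuracy(pp, 901, 0.5), "no channels")
})

test_that("band_report extracts contiguous intervals above threshold", {
  prof <- tibble::tibble(
    wavenumber = seq(400, 478, by = 2),
    vip = c(rep(0.2, 10), 1.1, 1.5, 1.2, rep(0.3, 10), 2.0, 2.4, rep(0.1, 15))
  )
  class(prof) <- c("vip_profile", class(prof))
  br <- band_report(prof, threshold = 1)
  expect_equal(nrow(br), 2)
  expect_equal(br$low, c(420, 446))
  expect_equal(br$high, c(424, 448))
  expect_equal(br$peak_position, c(422, 448))
  expect_equal(br$peak_vip, c(1.5, 2.4))

  flat <- prof; flat$vip <- rep(0.5, nrow(flat))
  expect_equal(nrow(band_report(flat, 1)), 0)
  whole <- band_report(flat, 0)
  expect_equal(nrow(whole), 1)
  expect_equal(c(whole$low, whole$high), c(400, 478))
  expect_error(band_report(prof, -1), "threshold")
})

test_that("subject-vote variant aggregates replicates before scoring", {
  ds <- generate_cohort(small_config(seed = 51))
  pp <- preprocess_dataset(ds)
  res <- run_protocol(pp, n_iterations = 3, k = 4, base_seed = 9,
                      subject_vote = TRUE)
  expect_equal(nrow(res$per_iteration), 6)
  expect_true(all(res$per_iteration$accuracy >= 0 &
                    res$per_iteration$accuracy <= 1))
})
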