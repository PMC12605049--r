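test_that("the learning-rate schedule ramps linearly then follows the cosine closed form", {
  cfg <- train_config(epochs = 10)
  total <- 1000
  warm <- ceiling(0.05 * total)
  expect_equal(lr_schedule(0, total, cfg), 0)
  expect_equal(lr_schedule(warm, total, cfg), 5e-4)
  # linear in the warm-up span
  expect_equal(lr_schedule(warm / 2, total, cfg), 5e-4 / 2)
  # closed-form cosine mid-decay
  mid <- warm + (total - warm) / 2
  expect_equal(lr_schedule(mid, total, cfg),
               5e-4 * 0.5 * (1 + cos(pi / 2)), tolerance = 1e-12)
  # monotone non-increasing after warm-up, ends at 0
  lrs <- lr_schedule(warm:total, total, cfg)
  expect_true(all(diff(lrs) <= 1e-15))
  expect_equal(lr_schedule(total, total, cfg), 0, tolerance = 1e-12)
})

test_that("patient-dependent splits are stratified ~80/20 partitions, reproducibly", {
  ds <- make_toy_windows(n_per_class = 25, n_subjects = 2)  # 50/50 per subject
  plan <- split_patient_dependent(ds, seed = 3)
  expect_identical(length(plan$folds), 2L)
  for (f in plan$folds) {
    si <- which(ds$subject_ids == f$subject)
    expect_identical(sort(c(f$train, f$test)), si)
    expect_length(intersect(f$train, f$test), 0)
    expect_identical(length(f$test), 10L)  # floor(25/5) per class
    expect_identical(sum(ds$labels[f$test] == 1L), 5L)
    expect_identical(sum(ds$labels[f$train] == 1L), 20L)
  }
  plan2 <- split_patient_dependent(ds, seed = 3)
  expect_identical(plan, plan2)
  plan3 <- split_patient_dependent(ds, seed = 4)
  expect_false(identical(plan, plan3))

  # a subject missing one class is flagged and skipped
  ds1 <- ds
  ds1$labels[ds1$subject_ids == "T02"] <- 0L
  expect_warning(p <- split_patient_dependent(ds1, seed = 1), "lacks one class")
  expect_identical(p$skipped, "T02")
  expect_identical(length(p$folds), 1L)
})

test_that("LOSO folds cover every subject exactly once with zero leakage", {
  ds <- make_toy_windows(n_per_class = 5, n_subjects = 5)
  plan <- split_loso(ds)
  expect_identical(length(plan$folds), 5L)
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_identical(sort(all_test), seq_along(ds$labels))
  for (f in plan$folds) {
    expect_true(all(ds$subject_ids[f$test] == f$subject))
    expect_false(f$subject %in% ds$subject_ids[f$train])
    expect_length(intersect(f$train, f$test), 0)
  }
  one <- make_toy_windows(n_per_class = 4, n_subjects = 1)
  expect_error(split_loso(one), "at least 2")
})

test_that("metrics match the defining formulas, brute force, and flag zero denominators", {
  r <- metrics_from_counts(3, 1, 1, 5)
  expect_equal(r$accuracy, 0.8)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$f1, 0.75)
  expect_equal(r$specificity, 5 / 6, tolerance = 1e-4)
  expect_length(r$undefined, 0)

  perfect <- metrics_from_counts(10, 0, 0, 10)
  expect_true(all(c(perfect$accuracy, perfect$sensitivity, perfect$f1,
                    perfect$specificity) == 1))

  nopos <- metrics_from_counts(0, 2, 0, 8)
  expect_true("sensitivity" %in% nopos$undefined)
  expect_true(is.na(nopos$sensitivity))

  # brute-force confusion loop on 1000 random prediction/label vectors
  set.seed(51)
  pred <- sample(0:1, 1000, replace = TRUE)
  lab <- sample(0:1, 1000, replace = TRUE)
  cc <- confusion_counts(pred, lab)
  btp <- bfp <- bfn <- btn <- 0L
  for (i in seq_len(1000)) {
    if (pred[i] == 1 && lab[i] == 1) btp <- btp + 1L
    else if (pred[i] == 1 && lab[i] == 0) bfp <- bfp + 1L
    else if (pred[i] == 0 && lab[i] == 1) bfn <- bfn + 1L
    else btn <- btn + 1L
  }
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(btp, bfp, bfn, btn))
  m <- metrics_from_counts(cc$tp, cc$fp, cc$fn, cc$tn)
  expect_equal(m$accuracy, (btp + btn) / 1000)

  # F1 equals the harmonic-mean form wherever both are defined
  for (k in 1:20) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    mm <- metrics_from_counts(tp, fp, fn, 5)
    if (tp + fp > 0 && tp + fn > 0 && tp > 0) {
      P <- tp / (tp + fp); R <- tp / (tp + fn)
      expect_equal(mm$f1, 2 * P * R / (P + R), tolerance = 1e-12)
    }
  }
})

test_that("per-subject aggregation uses population sd and excludes undefined entries", {
  r1 <- metrics_from_counts(9, 1, 0, 9)   # acc 0.9..., spec 0.9
  r2 <- metrics_from_counts(10, 0, 0, 10) # all 1
  agg <- aggregate_metrics(list(r1, r2))
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, mean(c(18 / 19, 1)))
  expect_equal(acc$sd, abs(18 / 19 - 1) / 2)  # population sd of two points

  two <- aggregate_metrics(list(metrics_from_counts(9, 0, 1, 10),
                                metrics_from_counts(10, 0, 0, 10)))
  expect_equal(two[two$metric == "accuracy", "mean"], mean(c(0.95, 1)))

  single <- aggregate_metrics(list(r2))
  expect_equal(single$sd, rep(0, 4))

  part <- aggregate_metrics(list(metrics_from_counts(0, 0, 0, 10), r2))
  sens <- part[part$metric == "sensitivity", ]
  expect_identical(sens$n_excluded, 1L)
  expect_equal(sens$mean, 1)
  allundef <- aggregate_metrics(list(metrics_from_counts(0, 0, 0, 10)))
  expect_true(is.na(allundef[allundef$metric == "sensitivity", "mean"]))
  expect_identical(allundef[allundef$metric == "sensitivity", "n_excluded"], 1L)
})

test_that("training descends, is reproducible, and follows the recorded lr schedule", {
  ds <- make_toy_windows(n_per_class = 16, n_subjects = 2)
  cfg <- model_config(stage_depths = c(1, 1, 1, 1), stage_widths = c(4, 4, 4, 4),
                      input_channels = 9,
                      attention = cprsca_config(reduction_ratio = 4))
  tc <- train_config(epochs = 3, seed = 7)
  m1 <- build_model(cfg, seed = 2)
  r1 <- train_model(m1, ds, config = tc)
  expect_lt(r1$history$loss[3], r1$history$loss[1])

  m2 <- build_model(cfg, seed = 2)
  r2 <- train_model(m2, ds, config = tc)
  expect_identical(r1$history, r2$history)

  total <- nrow(r1$history) * ceiling(length(ds$labels) / tc$batch_size)
  expect_equal(r1$lr_trace, lr_schedule(seq_len(total) - 1, total, tc),
               tolerance = 1e-12)

  ev <- evaluate_model(m1, ds)
  expect_identical(ev$tp + ev$fp + ev$fn + ev$tn, length(ds$labels))
})
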