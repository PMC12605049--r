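#' @title Training and evaluation protocols
#' @description
#' The two evaluation paradigms for window-level seizure detection —
#' per-subject 4:1 patient-dependent splits and leave-one-subject-out
#' (LOSO) — plus the training loop (cross-entropy, AdamW, warm-up +
#' cosine decay), confusion-matrix metrics and per-patient aggregation.
#' @name experiments
NULL

#' Training configuration
#'
#' @param batch_size minibatch size (default 4).
#' @param epochs training epochs (default 50; desk-scale experiments in
#'   this package use 5).
#' @param base_lr peak learning rate (default 5e-4).
#' @param warmup_frac fraction of total steps used for the linear warm-up
#'   from 0 to `base_lr` (default 0.05).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param beta1,beta2 AdamW moment decay rates.
#' @param eps AdamW denominator stabilizer.
#' @param seed RNG seed controlling shuffling (and, with the model seed,
#'   full reproducibility).
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, epochs = 50L, base_lr = 5e-4,
                         warmup_frac = 0.05, weight_decay = 0.01,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1L) {
  stopifnot(batch_size >= 1L, epochs >= 1L, base_lr > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), base_lr = base_lr,
                 warmup_frac = warmup_frac, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule: linear warm-up then cosine decay
#'
#' Ramps linearly from 0 at step 0 to `base_lr` at the end of the warm-up
#' span (`warmup_frac` of `total_steps`), then decays along a half cosine
#' to 0 at the final step; monotone non-increasing after warm-up.
#'
#' @param step 0-based optimization step.
#' @param total_steps total optimization steps of the run.
#' @param config a [train_config()].
#' @return learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, config = train_config()) {
  warm <- max(1L, as.integer(ceiling(config$warmup_frac * total_steps)))
  ifelse(step < warm,
         config$base_lr * step / warm,
         config$base_lr * 0.5 *
           (1 + cos(pi * (step - warm) / max(1L, total_steps - warm))))
}

# ---- split plans --------------------------------------------------------

#' Per-subject stratified 4:1 split (patient-dependent protocol)
#'
#' For each subject, splits that subject's windows into ~80% train / ~20%
#' test, stratified by label (the test side takes `floor(n/5)` per class,
#' with a floor of 1). One fold per subject; deterministic given the seed.
#' Subjects missing a class are skipped with a warning record.
#'
#' @param ds a labeled `window_dataset`.
#' @param ratio train fraction (default 0.8).
#' @param seed RNG seed.
#' @return object of class `split_plan` with `mode`, `folds` (each a list
#'   with `subject`, `train`, `test` window indices) and `skipped`.
#' @export
split_patient_dependent <- function(ds, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "window_dataset"), !anyNA(ds$labels))
  set.seed(as.integer(seed))
  folds <- list(); skipped <- character(0)
  for (sid in unique(ds$subject_ids)) {
    si <- which(ds$subject_ids == sid)
    test <- integer(0)
    classes <- sort(unique(ds$labels[si]))
    if (length(classes) < 2L) {
      warning("subject ", sid, " lacks one class; skipped from patient-dependent plan")
      skipped <- c(skipped, sid)
      next
    }
    for (cl in classes) {
      ci <- si[ds$labels[si] == cl]
      n_test <- max(1L, round(length(ci) * (1 - ratio)))
      test <- c(test, sample(ci, n_test))
    }
    folds[[length(folds) + 1L]] <- list(subject = sid,
                                        train = sort(setdiff(si, test)),
                                        test = sort(test))
  }
  new_split_plan("patient_dependent", folds, skipped, ds)
}

#' Leave-one-subject-out split plan
#'
#' One fold per subject: fold k tests on subject k's windows only and
#' trains on every other subject's windows.
#'
#' @param ds a labeled `window_dataset` with >= 2 subjects.
#' @return a `split_plan`.
#' @export
split_loso <- function(ds) {
  stopifnot(inherits(ds, "window_dataset"))
  subjects <- unique(ds$subject_ids)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  folds <- lapply(subjects, function(sid) {
    list(subject = sid,
         train = which(ds$subject_ids != sid),
         test = which(ds$subject_ids == sid))
  })
  new_split_plan("loso", folds, character(0), ds)
}

new_split_plan <- function(mode, folds, skipped, ds) {
  for (f in folds) {
    if (length(intersect(f$train, f$test)) > 0)
      stop("internal error: train/test overlap in fold for subject ", f$subject)
  }
  structure(list(mode = mode, folds = folds, skipped = skipped,
                 n_windows = length(ds$labels)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan (%s): %d fold(s)", x$mode, length(x$folds)))
  if (length(x$skipped)) cat(",", length(x$skipped), "subject(s) skipped")
  cat("\n")
  invisible(x)
}

# ---- optimizer and loss -------------------------------------------------

adamw_state <- function(modules) {
  lapply(modules, function(m)
    lapply(stats::setNames(m$params, m$params), function(p) {
      z <- array(0, dim = dim(m[[p]]) %||% length(m[[p]]))
      list(m = z, v = z)
    }))
}

adamw_step <- function(modules, state, lr, config, t) {
  b1 <- config$beta1; b2 <- config$beta2
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  for (i in seq_along(modules)) {
    mod <- modules[[i]]
    for (p in mod$params) {
      g <- mod[[paste0("g_", p)]]
      st <- state[[i]][[p]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      state[[i]][[p]] <- st
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + config$eps)
      old <- mod[[p]]
      newv <- old - lr * (upd + config$weight_decay * old)
      dim(newv) <- dim(old)  # keep vector params as plain vectors
      mod[[p]] <- newv
    }
  }
  state
}

# softmax cross-entropy over a (K x n) logit matrix; labels in 0:(K-1)
softmax_xent <- function(logits, labels) {
  n <- ncol(logits)
  mx <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, mx))
  p <- sweep(e, 2L, colSums(e), "/")
  li <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[li], 1e-12)))
  dl <- p
  dl[li] <- dl[li] - 1
  list(loss = loss, dlogits = dl / n, prob = p)
}

windows_to_tensor <- function(ds, idx) {
  x <- ds$windows[idx, , , drop = FALSE]
  d <- dim(x)
  aperm(array(x, c(d[1], 1L, d[2], d[3])), c(2L, 3L, 4L, 1L))  # (1,E,S,n)
}

#' Train a model on a set of windows
#'
#' Minimizes softmax cross-entropy with AdamW under the warm-up + cosine
#' learning-rate schedule, shuffling each epoch with the config seed.
#' Reproducible: two runs with the same seeds give identical loss
#' histories. Aborts with a diagnostic if the loss turns non-finite.
#'
#' @param model a model from [build_model()] (trained in place and also
#'   returned).
#' @param ds a labeled `window_dataset`.
#' @param train_idx window indices to train on.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model`, `history` (per-epoch loss/accuracy) and
#'   `lr_trace` (the learning rate at every optimization step).
#' @export
train_model <- function(model, ds, train_idx = seq_along(ds$labels),
                        config = train_config(), verbose = FALSE) {
  stopifnot(!anyNA(ds$labels[train_idx]))
  modules <- collect_modules(model)
  state <- adamw_state(modules)
  n <- length(train_idx)
  steps_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- steps_per_epoch * config$epochs
  set.seed(config$seed)
  history <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  lr_trace <- numeric(0)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0; ep_correct <- 0L
    for (b in seq_len(steps_per_epoch)) {
      bi <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
      bi <- bi[!is.na(bi)]
      x <- windows_to_tensor(ds, bi)
      y <- ds$labels[bi]
      logits <- model$forward_tensor(x)
      ce <- softmax_xent(logits, y)
      if (!is.finite(ce$loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d step %d", ep, b))
      zero_grads(modules)
      model$backward_tensor(ce$dlogits)
      lr <- lr_schedule(step, total_steps, config)
      lr_trace <- c(lr_trace, lr)
      step <- step + 1L
      state <- adamw_step(modules, state, lr, config, step)
      ep_loss <- ep_loss + ce$loss * length(bi)
      pred <- max.col(t(ce$prob), ties.method = "first") - 1L
      ep_correct <- ep_correct + sum(pred == y)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n,
                                         accuracy = ep_correct / n))
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f acc %.3f", ep, config$epochs,
                      ep_loss / n, ep_correct / n))
  }
  list(model = model, history = history, lr_trace = lr_trace)
}

# ---- metrics ------------------------------------------------------------

#' Confusion-matrix metrics for binary seizure detection
#'
#' Accuracy, sensitivity (true-positive rate), F1 score
#' (`2TP / (2TP + FP + FN)`), and specificity (true-negative rate) from
#' the four confusion counts. Ratios with a zero denominator are flagged
#' undefined (NA), never coerced to 0.
#'
#' @param tp,fp,fn,tn non-negative confusion counts.
#' @return object of class `metrics_report`: the counts, the four metrics
#'   and `undefined`, the names of metrics with zero denominators.
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(tp = tp, fp = fp, fn = fn, tn = tn,
            accuracy = ratio(tp + tn, tp + tn + fp + fn),
            sensitivity = ratio(tp, tp + fn),
            f1 = ratio(2 * tp, 2 * tp + fp + fn),
            specificity = ratio(tn, tn + fp))
  m$undefined <- names(which(vapply(m[c("accuracy", "sensitivity", "f1",
                                        "specificity")], is.na, logical(1))))
  structure(m, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%d | acc %.4f sens %s F1 %s spec %s\n",
              x$tp, x$fp, x$fn, x$tn, x$accuracy,
              format_metric(x$sensitivity), format_metric(x$f1),
              format_metric(x$specificity)))
  invisible(x)
}

format_metric <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)

#' Confusion counts for binary predictions
#'
#' @param predictions integer vector of 0/1 predictions.
#' @param labels integer vector of 0/1 reference labels.
#' @return named list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  list(tp = sum(predictions == 1L & labels == 1L),
       fp = sum(predictions == 1L & labels == 0L),
       fn = sum(predictions == 0L & labels == 1L),
       tn = sum(predictions == 0L & labels == 0L))
}

#' Evaluate a model on test windows
#'
#' Predicts by argmax over the two logits (tie broken toward the negative
#' class) and reports the confusion counts and derived metrics.
#'
#' @param model a trained model.
#' @param ds a labeled `window_dataset`.
#' @param test_idx window indices to evaluate.
#' @param batch_size inference batch size.
#' @return a [metrics_from_counts()] report.
#' @export
evaluate_model <- function(model, ds, test_idx = seq_along(ds$labels),
                           batch_size = 32L) {
  stopifnot(!anyNA(ds$labels[test_idx]))
  preds <- integer(0)
  for (chunk in split(test_idx, ceiling(seq_along(test_idx) / batch_size))) {
    logits <- model_forward(model, ds$windows[chunk, , , drop = FALSE])
    preds <- c(preds, ifelse(logits[, 2] > logits[, 1], 1L, 0L))
  }
  cc <- confusion_counts(preds, ds$labels[test_idx])
  metrics_from_counts(cc$tp, cc$fp, cc$fn, cc$tn)
}

#' Aggregate per-subject metrics
#'
#' Unweighted mean and population standard deviation of each metric
#' across subjects, excluding flagged-undefined entries (exclusion counts
#' are reported, not imputed as 0).
#'
#' @param reports list of [metrics_from_counts()] reports, one per subject.
#' @return data.frame with metric, mean, sd and n_excluded columns.
#' @export
aggregate_metrics <- function(reports) {
  metrics <- c("accuracy", "sensitivity", "f1", "specificity")
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) r[[m]], numeric(1))
    ok <- !is.na(v)
    data.frame(metric = m,
               mean = if (any(ok)) mean(v[ok]) else NA_real_,
               sd = if (any(ok)) sqrt(mean((v[ok] - mean(v[ok]))^2)) else NA_real_,
               n_excluded = sum(!ok))
  })
  do.call(rbind, rows)
}

# ---- full protocols -----------------------------------------------------

#' Run a full evaluation protocol on a window dataset
#'
#' Patient-dependent mode: every subject's windows are split 4:1 within
#' subject; one shared model is trained on the union of all training
#' windows (patient identities are mixed, in contrast to the
#' patient-independent setting where they are strictly separated) and
#' evaluated per subject on the held-out 20%. LOSO mode: one model per
#' fold, trained from a fresh fold-seeded initialization on all other
#' subjects and tested on the held-out subject. Per-subject metrics are
#' aggregated as mean and population sd.
#'
#' @param ds a labeled `window_dataset`.
#' @param mode `"patient_dependent"` or `"loso"`.
#' @param model_cfg a [model_config()] (default [tiny_model_config()]
#'   sized to the dataset's channel count).
#' @param config a [train_config()].
#' @param model_seed base seed for per-fold model initialization.
#' @param verbose print fold progress.
#' @return list with `plan`, `per_subject` (data.frame of counts and
#'   metrics), `reports`, and `aggregate`.
#' @export
run_protocol <- function(ds, mode = c("patient_dependent", "loso"),
                         model_cfg = NULL, config = train_config(epochs = 5L),
                         model_seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(model_cfg))
    model_cfg <- tiny_model_config(input_channels = dim(ds$windows)[2])
  plan <- if (mode == "loso") split_loso(ds)
  else split_patient_dependent(ds, seed = config$seed)
  reports <- list()
  if (mode == "patient_dependent") {
    train_all <- sort(unlist(lapply(plan$folds, `[[`, "train")))
    model <- build_model(model_cfg, seed = model_seed)
    if (verbose) message(sprintf("[%s] training shared model on %d windows",
                                 mode, length(train_all)))
    train_model(model, ds, train_all, config)
    for (fold in plan$folds)
      reports[[fold$subject]] <- evaluate_model(model, ds, fold$test)
  } else {
    for (k in seq_along(plan$folds)) {
      fold <- plan$folds[[k]]
      if (verbose) message(sprintf("[%s] fold %d/%d (test subject %s)",
                                   mode, k, length(plan$folds), fold$subject))
      model <- build_model(model_cfg, seed = model_seed + k)
      fold_cfg <- config
      fold_cfg$seed <- config$seed + k
      train_model(model, ds, fold$train, fold_cfg)
      reports[[fold$subject]] <- evaluate_model(model, ds, fold$test)
    }
  }
  per_subject <- do.call(rbind, lapply(names(reports), function(sid) {
    r <- reports[[sid]]
    data.frame(subject = sid, tp = r$tp, fp = r$fp, fn = r$fn, tn = r$tn,
               accuracy = r$accuracy, sensitivity = r$sensitivity,
               f1 = r$f1, specificity = r$specificity)
  }))
  list(plan = plan, per_subject = per_subject, reports = reports,
       aggregate = aggregate_metrics(reports))
}
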