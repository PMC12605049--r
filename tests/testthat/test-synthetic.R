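test_that("generator outputs are pure functions of their seeds", {
  p <- subject_params(seed = 12, n_electrodes = 4)
  a <- gen_background(5, p, 250)
  b <- gen_background(5, p, 250)
  expect_identical(a, b)

  spec <- cohort_spec(n_subjects = 2, recording_s = 200, seizures_per_subject = 1,
                      seizure_duration_s = c(10, 15), sampling_rate = 250,
                      electrodes = c("FP1", "F7", "F3", "C3"), master_seed = 4)
  r1 <- gen_recording(spec, 1)
  r2 <- gen_recording(spec, 1)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$seizures, r2$seizures)
})

test_that("background noise has the requested spectral slope and amplitude scaling", {
  p0 <- subject_params(pink_exponent = 0, seed = 3, n_electrodes = 2,
                       channel_mixing = diag(2))
  x <- gen_background(40, p0, 250)
  sp <- stats::spec.pgram(stats::ts(x[1, ], frequency = 250), plot = FALSE,
                          taper = 0, spans = 11)
  keep <- sp$freq > 1 & sp$freq < 100
  slope <- stats::coef(stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2]
  expect_lt(abs(slope), 0.3)

  p1 <- subject_params(pink_exponent = 1.5, seed = 3, n_electrodes = 2,
                       channel_mixing = diag(2))
  x1 <- gen_background(40, p1, 250)
  sp1 <- stats::spec.pgram(stats::ts(x1[1, ], frequency = 250), plot = FALSE,
                           taper = 0, spans = 11)
  slope1 <- stats::coef(stats::lm(log(sp1$spec[keep]) ~ log(sp1$freq[keep])))[2]
  expect_lt(slope1, -0.8)

  # linear amplitude scaling
  pa <- subject_params(background_amp = 20, seed = 8, n_electrodes = 3)
  pb <- subject_params(background_amp = 60, seed = 8, n_electrodes = 3)
  expect_equal(3 * gen_background(4, pa, 250), gen_background(4, pb, 250),
               tolerance = 1e-9)
})

test_that("ictal segments show the spike-and-wave rate and elevated RMS", {
  p <- subject_params(seed = 21, n_electrodes = 3, ictal_amp_ratio = 3)
  seiz <- gen_seizure_segment(20, p, 250)
  bg <- gen_background(20, p, 250)
  expect_gt(sqrt(mean(seiz^2)) / sqrt(mean(bg^2)), 1)

  sp <- stats::spec.pgram(stats::ts(seiz[1, ], frequency = 250), plot = FALSE,
                          taper = 0)
  peak <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(peak - p$spikewave_freq), 0.3)

  expect_identical(ncol(gen_seizure_segment(0, p, 250)), 0L)
})

test_that("recordings embed the requested seizures with exact annotations", {
  spec <- cohort_spec(n_subjects = 2, recording_s = 400, seizures_per_subject = 3,
                      seizure_duration_s = c(15, 25), sampling_rate = 250,
                      electrodes = montage_electrodes_15(), master_seed = 6)
  rec <- gen_recording(spec, 1)
  expect_identical(nrow(rec$seizures), 3L)
  expect_true(all(rec$seizures$onset_s < rec$seizures$offset_s))
  expect_true(all(rec$seizures$offset_s <= 400))
  # non-overlapping after merge means ingest kept all three
  expect_true(all(diff(rec$seizures$onset_s) > 0))

  # end-to-end: labeling recovers ictal windows only inside annotations
  ds <- label_windows(segment_windows(resample_recording(rec, 250), 3), guard_s = 30)
  pos_t <- ds$start_times[ds$labels == 1L]
  inside <- vapply(pos_t, function(t0) any(t0 >= rec$seizures$onset_s &
                                             t0 + 3 <= rec$seizures$offset_s), logical(1))
  expect_true(all(inside))
})

test_that("cohorts have distinct subjects with real between-subject variability", {
  spec <- cohort_spec(n_subjects = 5, recording_s = 120, seizures_per_subject = 1,
                      seizure_duration_s = c(10, 12), sampling_rate = 250,
                      electrodes = c("FP1", "F7", "F3", "C3"), master_seed = 9)
  cohort <- gen_cohort(spec)
  expect_identical(length(cohort), 5L)
  ids <- vapply(cohort, function(r) r$subject_id, "")
  expect_identical(anyDuplicated(ids), 0L)
  rms <- vapply(cohort, function(r) sqrt(mean(r$signal^2)), numeric(1))
  expect_gt(stats::var(rms), 0)
  cohort2 <- gen_cohort(spec)
  expect_identical(cohort[[3]]$signal, cohort2[[3]]$signal)
})

test_that("a trivial RMS threshold separates synthetic classes (task solvability)", {
  ds <- get_synth_dataset()
  rms <- sqrt(apply(ds$windows^2, 1, mean))
  thr <- mean(tapply(rms, ds$labels, mean))
  acc <- mean((rms > thr) == (ds$labels == 1L))
  expect_gt(acc, 0.9)
})

test_that("synthetic recordings survive an EDF round trip", {
  spec <- cohort_spec(n_subjects = 2, recording_s = 60, seizures_per_subject = 1,
                      seizure_duration_s = c(10, 12), sampling_rate = 250,
                      electrodes = c("FP1", "F7", "F3"), master_seed = 2)
  rec <- gen_recording(spec, 2)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path, annotations = rec$seizures)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_lt(max(abs(back$signal - rec$signal)) / max(abs(rec$signal)), 1e-3)
  expect_equal(back$seizures, rec$seizures)
})
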