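test_that("EDF files round-trip signals, labels and rate within quantization error", {
  set.seed(41)
  rec <- make_toy_recording(fs = 256, dur = 10, labels = c("C3", "C4"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path, subject_id = "TST")
  expect_identical(dim(back$signal), c(2L, 2560L))
  expect_identical(back$channel_labels, c("C3", "C4"))
  expect_equal(back$sampling_rate, 256)
  # 16-bit quantization: error bounded by one digital step
  step <- max(abs(rec$signal)) * 1.0001 / 32767
  expect_lt(max(abs(back$signal - rec$signal)), 2 * step)

  expect_error(read_edf(tempfile()), "does not exist")
})

test_that("annotations are validated, sorted and merged on ingest", {
  rec <- make_toy_recording(dur = 60)
  expect_error(eeg_recording("A", rec$channel_labels, 100, rec$signal,
                             data.frame(onset_s = 30, offset_s = 20)),
               "onset >= offset")
  expect_error(eeg_recording("A", rec$channel_labels, 100, rec$signal,
                             data.frame(onset_s = 50, offset_s = 80)),
               "outside recording duration")
  merged <- eeg_recording("A", rec$channel_labels, 100, rec$signal,
                          data.frame(onset_s = c(15, 10), offset_s = c(25, 20)))
  expect_identical(nrow(merged$seizures), 1L)
  expect_equal(merged$seizures$onset_s, 10)
  expect_equal(merged$seizures$offset_s, 25)

  # sidecar CSV path ingestion
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(onset_s = 5, offset_s = 12), csv, row.names = FALSE)
  back <- read_edf(path, annotations = csv)
  expect_equal(back$seizures$onset_s, 5)
})

test_that("select_channels reorders exactly, errors on missing labels, and is idempotent", {
  rec <- make_toy_recording(labels = c("FP1", "F7", "F3", "C3"))
  expect_identical(select_channels(rec, rec$channel_labels)$signal, rec$signal)
  revd <- select_channels(rec, rev(rec$channel_labels))
  expect_identical(revd$signal, rec$signal[4:1, ])
  expect_identical(revd$channel_labels, rev(rec$channel_labels))
  twice <- select_channels(select_channels(rec, c("F3", "FP1")), c("F3", "FP1"))
  expect_identical(twice$signal, rec$signal[c(3, 1), ])
  expect_error(select_channels(rec, c("FP1", "O2")), "O2")
  expect_identical(length(chb_mit_18_channels()), 18L)
})

test_that("bipolar montage computes anode-minus-cathode derivations", {
  fs <- 100
  sig <- rbind(FP1 = rep(3, fs), F7 = rep(1, fs), A = rep(2, fs))
  rec <- eeg_recording("M", c("FP1", "F7", "A"), fs, sig)
  out <- build_bipolar_montage(rec, "FP1-F7")
  expect_identical(out$channel_labels, "FP1-F7")
  expect_true(all(out$signal == 2))
  self_diff <- build_bipolar_montage(rec, "A-A")
  expect_true(all(self_diff$signal == 0))
  expect_error(build_bipolar_montage(rec, "FP1-O2"), "O2")

  # the standard 15-electrode set supports all 12 derivations
  rec15 <- make_toy_recording(labels = montage_electrodes_15(), dur = 5)
  m12 <- build_bipolar_montage(rec15, bipolar_pairs_12())
  expect_identical(nrow(m12$signal), 12L)
})

test_that("resampling preserves duration, identity case, and spectral peaks", {
  rec <- make_toy_recording(fs = 500, dur = 10)
  down <- resample_recording(rec, 256)
  expect_identical(ncol(down$signal), 2560L)
  expect_equal(down$sampling_rate, 256)

  expect_identical(resample_recording(rec, 500), rec)
  expect_error(resample_recording(rec, 600), "upsampling")

  # pure 5 Hz sinusoid survives 500 -> 256 Hz with its peak intact
  tt <- seq_len(5000) / 500
  sine <- eeg_recording("S", "C3", 500, matrix(sin(2 * pi * 5 * tt), 1))
  ds <- resample_recording(sine, 256)
  sp <- stats::spec.pgram(stats::ts(ds$signal[1, ], frequency = 256),
                          plot = FALSE, taper = 0)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 5), 0.2)

  # annotations pass through untouched (they live in seconds)
  rec2 <- make_toy_recording(fs = 500, dur = 10,
                             seizures = data.frame(onset_s = 2, offset_s = 4))
  expect_identical(resample_recording(rec2, 256)$seizures, rec2$seizures)
})

test_that("windowing enumerates complete windows and drops the partial tail", {
  rec <- make_toy_recording(fs = 256, dur = 30, labels = sprintf("E%02d", 1:18))
  ds <- segment_windows(rec, 3, 3)
  expect_identical(dim(ds$windows), c(10L, 18L, 768L))
  expect_equal(ds$start_times, seq(0, 27, by = 3))

  short <- make_toy_recording(fs = 100, dur = 2.9)
  expect_identical(dim(segment_windows(short, 3)$windows)[1], 0L)

  seven <- make_toy_recording(fs = 100, dur = 7)
  ds7 <- segment_windows(seven, 3, 3)
  expect_identical(dim(ds7$windows)[1], 2L)
  expect_equal(ds7$start_times, c(0, 3))
  expect_identical(ds7$windows[1, , ], seven$signal[, 1:300])
  expect_identical(ds7$windows[2, , ], seven$signal[, 301:600])
})

test_that("labeling is pure-in / pure-out with guard, and accounts for every window", {
  rec <- make_toy_recording(fs = 100, dur = 300,
                            seizures = data.frame(onset_s = 100, offset_s = 110))
  ds <- segment_windows(rec, 3, 1)
  lab <- label_windows(ds, guard_s = 60)
  total <- dim(ds$windows)[1]
  expect_identical(dim(lab$windows)[1] + attr(lab, "n_discarded"), total)

  # a window fully inside the seizure is ictal
  expect_true(all(lab$labels[lab$start_times >= 100 & lab$start_times + 3 <= 110] == 1L))
  # a window straddling onset was discarded
  expect_false(any(lab$start_times < 100 & lab$start_times + 3 > 100))
  # negatives respect the 60 s guard
  neg <- lab$start_times[lab$labels == 0L]
  expect_true(all(neg + 3 <= 40 | neg >= 170))

  # no seizures: everything is interictal
  quiet <- make_toy_recording(fs = 100, dur = 60)
  lq <- label_windows(segment_windows(quiet, 3), guard_s = 60)
  expect_true(all(lq$labels == 0L))
  expect_identical(attr(lq, "n_discarded"), 0L)
})

test_that("montage and windowing commute (linearity)", {
  rec <- make_toy_recording(fs = 100, dur = 12, labels = c("FP1", "F7", "F3"))
  pairs <- c("FP1-F7", "F7-F3")
  a <- segment_windows(build_bipolar_montage(rec, pairs), 3)
  b <- segment_windows(rec, 3)
  for (i in seq_len(dim(a$windows)[1])) {
    manual <- rbind(b$windows[i, 1, ] - b$windows[i, 2, ],
                    b$windows[i, 2, ] - b$windows[i, 3, ])
    expect_equal(a$windows[i, , ], manual, tolerance = 1e-12)
  }
})

test_that("class balancing undersamples negatives per subject, reproducibly", {
  ds <- make_toy_windows(n_per_class = 10, n_subjects = 2)
  ds$labels[ds$subject_ids == "T01" & ds$labels == 0][1:5] <- 0L  # no-op, clarity
  unbal <- ds
  unbal$windows <- unbal$windows[c(seq_len(40), 1:6), , ]
  unbal$labels <- c(ds$labels, rep(0L, 6))
  unbal$subject_ids <- c(ds$subject_ids, rep("T01", 6))
  unbal$start_times <- seq_along(unbal$labels)
  bal <- balance_classes(unbal, ratio = 1, seed = 9)
  for (sid in unique(bal$subject_ids))
    expect_identical(sum(bal$labels[bal$subject_ids == sid] == 0L),
                     sum(bal$labels[bal$subject_ids == sid] == 1L))
  bal2 <- balance_classes(unbal, ratio = 1, seed = 9)
  expect_identical(bal$start_times, bal2$start_times)
})

test_that("window stores round-trip with provenance", {
  ds <- make_toy_windows(n_per_class = 3)
  path <- tempfile(fileext = ".rds")
  save_windows(ds, path)
  back <- load_windows(path)
  expect_identical(back$windows, ds$windows)
  expect_identical(back$labels, ds$labels)
  prov <- attr(back, "provenance")
  expect_identical(prov$sampling_rate, ds$sampling_rate)
})
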