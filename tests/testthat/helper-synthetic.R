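# Shared synthetic fixtures, generated in code and cached for the test run.

.fixture_cache <- new.env()

# the default synthetic cohort, preprocessed to balanced labeled windows
# (bipolar montage, 256 Hz, 3 s windows) — the dataset used by the
# protocol and learning tests
get_synth_dataset <- function() {
  if (is.null(.fixture_cache$ds)) {
    cohort <- gen_cohort(cohort_spec(master_seed = 1L))
    .fixture_cache$ds <- preprocess_cohort(cohort, seed = 1L)
  }
  .fixture_cache$ds
}

# a small directly constructed window dataset: two classes separated by
# amplitude and rhythm, several subjects; cheap enough for split/training
# unit tests
make_toy_windows <- function(n_per_class = 16, n_subjects = 2,
                             electrodes = 9, samples = 64, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_class * n_subjects
  win <- array(0, c(n, electrodes, samples))
  labels <- integer(n)
  sids <- character(n)
  tt <- seq_len(samples) / samples
  i <- 1
  for (s in seq_len(n_subjects)) for (cl in 0:1) for (r in seq_len(n_per_class)) {
    base <- matrix(rnorm(electrodes * samples), electrodes, samples)
    if (cl == 1)
      base <- 4 * base + 6 * outer(rnorm(electrodes), sin(2 * pi * 9 * tt))
    win[i, , ] <- base
    labels[i] <- cl
    sids[i] <- sprintf("T%02d", s)
    i <- i + 1
  }
  structure(list(windows = win, labels = labels, subject_ids = sids,
                 start_times = seq_len(n) * 3, window_seconds = samples / 64,
                 sampling_rate = 64, channel_labels = paste0("CH", seq_len(electrodes))),
            class = "window_dataset")
}

# monopolar test recording with known content
make_toy_recording <- function(subject = "TST", fs = 100, dur = 30,
                               labels = c("FP1", "F7", "F3"),
                               seizures = NULL, seed = 3) {
  set.seed(seed)
  sig <- matrix(rnorm(length(labels) * fs * dur, sd = 20), length(labels))
  eeg_recording(subject, labels, fs, sig, seizures)
}
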