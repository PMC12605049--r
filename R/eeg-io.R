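#' @title EEG recordings, EDF I/O and preprocessing
#' @description
#' Reading and writing 16-bit EDF (European Data Format) files, seizure
#' interval annotations from a sidecar table, and the preprocessing chain
#' used for seizure detection: channel selection, bipolar montage
#' derivation, anti-aliased resampling to a common rate, fixed-length
#' windowing and ictal/interictal labeling. Signals are held in microvolts
#' as a channels x samples matrix.
#' @name eeg_io
NULL

#' Construct an EEG recording
#'
#' @param subject_id subject identifier string.
#' @param channel_labels character vector, one label per signal row;
#'   normalized to upper case with whitespace stripped.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param signal channels x samples numeric matrix in microvolts.
#' @param seizures data.frame with columns `onset_s`, `offset_s` (seconds
#'   from recording start), or NULL. Intervals are validated, sorted and
#'   overlaps merged.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, channel_labels, sampling_rate, signal,
                          seizures = NULL) {
  channel_labels <- toupper(trimws(channel_labels))
  signal <- as.matrix(signal)
  if (length(channel_labels) != nrow(signal))
    stop("channel label count must equal signal row count")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  dur <- ncol(signal) / sampling_rate
  seizures <- normalize_seizures(seizures, dur)
  structure(list(subject_id = as.character(subject_id),
                 channel_labels = channel_labels,
                 sampling_rate = sampling_rate,
                 signal = signal,
                 seizures = seizures),
            class = "eeg_recording")
}

normalize_seizures <- function(seizures, duration_s) {
  if (is.null(seizures) || nrow(as.data.frame(seizures)) == 0L)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  sz <- as.data.frame(seizures)[, c("onset_s", "offset_s")]
  if (any(!is.finite(sz$onset_s)) || any(!is.finite(sz$offset_s)))
    stop("malformed annotation: non-finite onset/offset")
  bad <- sz$onset_s >= sz$offset_s
  if (any(bad))
    stop(sprintf("malformed annotation: onset >= offset (%.3f, %.3f)",
                 sz$onset_s[which(bad)[1]], sz$offset_s[which(bad)[1]]))
  if (any(sz$onset_s < 0) || any(sz$offset_s > duration_s + 1e-9))
    stop("annotation interval outside recording duration")
  sz <- sz[order(sz$onset_s), , drop = FALSE]
  merged <- sz[1, , drop = FALSE]
  if (nrow(sz) > 1) for (i in 2:nrow(sz)) {
    k <- nrow(merged)
    if (sz$onset_s[i] <= merged$offset_s[k]) {
      merged$offset_s[k] <- max(merged$offset_s[k], sz$offset_s[i])
    } else {
      merged <- rbind(merged, sz[i, , drop = FALSE])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d channels x %.1f s @ %g Hz, %d seizure(s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal) / x$sampling_rate,
              x$sampling_rate, nrow(x$seizures)))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$signal) / rec$sampling_rate

# ---- EDF ----------------------------------------------------------------

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording to a 16-bit EDF file
#'
#' Emits a standard EDF file with 1-second data records. Physical scaling
#' is chosen per channel from the signal's range, so values round-trip to
#' within one digital quantization step. Seizure annotations are not
#' embedded; they travel in a sidecar table (see [read_edf()]).
#'
#' @param rec an [eeg_recording()]; sampling rate must be a whole number
#'   and the duration is truncated to whole seconds.
#' @param path output file path.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$signal)
  n_rec <- ncol(rec$signal) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF record (1 s)")
  sig <- rec$signal[, seq_len(n_rec * fs), drop = FALSE]

  pmax_ <- apply(abs(sig), 1L, max)
  pmax_ <- ifelse(pmax_ < 1e-6, 1, pmax_ * 1.0001)
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field("Startdate X", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256L + 256L * ns, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$channel_labels, pad_field, "", width = 16),
    rep(pad_field("", 80), ns),
    rep(pad_field("uV", 8), ns),
    vapply(-pmax_, function(v) pad_field(sprintf("%.8g", v), 8), ""),
    vapply(pmax_, function(v) pad_field(sprintf("%.8g", v), 8), ""),
    rep(pad_field(dmin, 8), ns),
    rep(pad_field(dmax, 8), ns),
    rep(pad_field("", 80), ns),
    rep(pad_field(fs, 8), ns),
    rep(pad_field("", 32), ns))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  gain <- (2 * pmax_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((sig[ch, cols] + pmax_[ch]) / gain[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  h <- list(version = trimws(rd(8)), patient = trimws(rd(80)),
            recording = trimws(rd(80)), startdate = rd(8), starttime = rd(8),
            header_bytes = as.integer(rd(8)), reserved = rd(44),
            n_records = as.integer(rd(8)),
            record_duration = as.numeric(rd(8)),
            n_signals = as.integer(rd(4)))
  if (is.na(h$n_signals) || h$n_signals < 1L)
    stop("unreadable EDF file: bad signal count in header")
  ns <- h$n_signals
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  h$labels <- fld(16); h$transducer <- fld(80); h$phys_dim <- fld(8)
  h$phys_min <- as.numeric(fld(8)); h$phys_max <- as.numeric(fld(8))
  h$dig_min <- as.numeric(fld(8)); h$dig_max <- as.numeric(fld(8))
  h$prefilter <- fld(80); h$samples_per_record <- as.integer(fld(8))
  rd(32 * ns)
  if (any(is.na(h$phys_min)) || any(is.na(h$samples_per_record)))
    stop("unreadable EDF file: malformed signal header")
  h
}

#' Read an EDF recording with sidecar seizure annotations
#'
#' Parses a 16-bit EDF file into an [eeg_recording()]: signals are scaled
#' to physical units (microvolts), channel labels are normalized to upper
#' case with whitespace stripped, and annotations — supplied as a
#' data.frame or CSV path with columns `onset_s`, `offset_s` — are
#' validated, sorted, and merged where they overlap.
#'
#' @param path EDF file path.
#' @param annotations NULL, a data.frame with `onset_s`/`offset_s` columns,
#'   or the path of a CSV file with those columns.
#' @param subject_id subject identifier; defaults to the EDF patient field
#'   (or the file name if that is empty).
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, annotations = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("unreadable EDF file: ", path, " does not exist")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  ns <- h$n_signals
  spr <- h$samples_per_record
  sig <- matrix(0, ns, h$n_records * max(spr))
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate per file")
  fs <- spr[1] / h$record_duration
  gain <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  for (r in seq_len(h$n_records)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      if (length(dig) < spr[ch]) stop("unreadable EDF file: truncated data record")
      cols <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      sig[ch, cols] <- (dig - h$dig_min[ch]) * gain[ch] + h$phys_min[ch]
    }
  }
  if (is.character(annotations) && length(annotations) == 1L) {
    if (!file.exists(annotations)) stop("annotation file not found: ", annotations)
    annotations <- utils::read.csv(annotations)
  }
  if (is.null(subject_id)) {
    subject_id <- if (nzchar(h$patient)) h$patient else basename(path)
  }
  eeg_recording(subject_id, h$labels, fs, sig, annotations)
}

# ---- channel operations -------------------------------------------------

#' Select and reorder channels
#'
#' Returns the recording restricted to `wanted` labels, rows reordered to
#' match `wanted` exactly; all other channels are dropped.
#'
#' @param rec an [eeg_recording()].
#' @param wanted ordered character vector of channel labels.
#' @return an [eeg_recording()] with `length(wanted)` channels.
#' @export
select_channels <- function(rec, wanted) {
  wanted <- toupper(trimws(wanted))
  idx <- match(wanted, rec$channel_labels)
  if (anyNA(idx))
    stop("channel(s) not present in recording: ",
         paste(wanted[is.na(idx)], collapse = ", "))
  eeg_recording(rec$subject_id, wanted, rec$sampling_rate,
                rec$signal[idx, , drop = FALSE], rec$seizures)
}

#' Derive a bipolar montage
#'
#' Builds differential channels: output channel i is the anode electrode's
#' signal minus the cathode's, labeled `"ANODE-CATHODE"`.
#'
#' @param rec an [eeg_recording()] of monopolar electrode signals.
#' @param pairs either a character vector of `"ANODE-CATHODE"` strings or a
#'   data.frame with columns `anode` and `cathode`.
#' @return an [eeg_recording()] with one channel per pair.
#' @export
build_bipolar_montage <- function(rec, pairs = bipolar_pairs_12()) {
  if (is.character(pairs)) {
    parts <- strsplit(toupper(trimws(pairs)), "-", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("montage pair strings must be 'ANODE-CATHODE'")
    pairs <- data.frame(anode = vapply(parts, `[`, "", 1),
                        cathode = vapply(parts, `[`, "", 2))
  }
  an <- match(toupper(trimws(pairs$anode)), rec$channel_labels)
  ca <- match(toupper(trimws(pairs$cathode)), rec$channel_labels)
  missing <- unique(c(pairs$anode[is.na(an)], pairs$cathode[is.na(ca)]))
  if (length(missing))
    stop("electrode(s) not resolvable in recording: ",
         paste(missing, collapse = ", "))
  out <- rec$signal[an, , drop = FALSE] - rec$signal[ca, , drop = FALSE]
  labels <- paste0(toupper(trimws(pairs$anode)), "-", toupper(trimws(pairs$cathode)))
  eeg_recording(rec$subject_id, labels, rec$sampling_rate, out, rec$seizures)
}

#' Resample a recording (downsampling only)
#'
#' Polyphase FIR resampling with an anti-alias low-pass (via
#' `signal::resample`). Annotations are in seconds and pass through
#' unchanged; the new sample count is `round(n * target / source)`.
#'
#' @param rec an [eeg_recording()].
#' @param target_hz target sampling rate; must not exceed the source rate.
#' @return an [eeg_recording()] at `target_hz`.
#' @export
resample_recording <- function(rec, target_hz = 256) {
  src <- rec$sampling_rate
  if (target_hz > src) stop("upsampling not supported: target rate above source rate")
  if (abs(target_hz - src) < 1e-9) return(rec)
  p <- as.integer(round(target_hz)); q <- as.integer(round(src))
  g <- gcd_int(p, q); p <- p %/% g; q <- q %/% g
  n_out <- round(ncol(rec$signal) * target_hz / src)
  out <- matrix(0, nrow(rec$signal), n_out)
  for (ch in seq_len(nrow(rec$signal))) {
    y <- signal::resample(rec$signal[ch, ], p, q)
    if (length(y) >= n_out) out[ch, ] <- y[seq_len(n_out)]
    else out[ch, seq_along(y)] <- y
  }
  eeg_recording(rec$subject_id, rec$channel_labels, target_hz, out, rec$seizures)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

# ---- windowing and labeling --------------------------------------------

#' Cut a recording into fixed-length windows
#'
#' Consecutive windows of `window_s` seconds starting at multiples of
#' `stride_s`; a trailing partial window is discarded. Windows carry their
#' absolute start times so they can be labeled against seizure intervals.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds (default 3).
#' @param stride_s hop between window starts in seconds (default: no
#'   overlap, `stride_s = window_s`).
#' @return object of class `window_dataset` with fields `windows`
#'   (n x channels x samples array), `labels` (NA until
#'   [label_windows()]), `subject_ids`, `start_times`, `window_seconds`,
#'   `sampling_rate`, `channel_labels`.
#' @export
segment_windows <- function(rec, window_s = 3, stride_s = window_s) {
  fs <- rec$sampling_rate
  spw <- as.integer(round(window_s * fs))
  hop <- as.integer(round(stride_s * fs))
  n_total <- ncol(rec$signal)
  starts <- if (n_total >= spw) seq(0L, n_total - spw, by = hop) else integer(0)
  n <- length(starts)
  win <- array(0, c(n, nrow(rec$signal), spw))
  for (i in seq_len(n))
    win[i, , ] <- rec$signal[, (starts[i] + 1L):(starts[i] + spw), drop = FALSE]
  structure(list(windows = win,
                 labels = rep(NA_integer_, n),
                 subject_ids = rep(rec$subject_id, n),
                 start_times = starts / fs,
                 window_seconds = window_s,
                 sampling_rate = fs,
                 channel_labels = rec$channel_labels,
                 seizures = rec$seizures),
            class = "window_dataset")
}

#' Label windows as ictal, interictal, or discard
#'
#' A window is labeled 1 (ictal) iff it lies entirely inside a seizure
#' interval, and 0 (interictal) iff it lies entirely outside every seizure
#' interval padded by a guard margin. Windows in neither category —
#' straddling a seizure boundary or inside the peri-ictal guard — are
#' discarded, keeping both classes pure.
#'
#' @param ds a `window_dataset` from [segment_windows()].
#' @param seizures data.frame with `onset_s`/`offset_s`; defaults to the
#'   annotations carried over from the source recording.
#' @param guard_s guard margin in seconds around each seizure excluded
#'   from the negative class (default 60).
#' @return the labeled `window_dataset`; attribute `n_discarded` counts
#'   dropped windows.
#' @export
label_windows <- function(ds, seizures = NULL, guard_s = 60) {
  stopifnot(inherits(ds, "window_dataset"))
  if (is.null(seizures)) seizures <- ds$seizures
  if (is.null(seizures)) seizures <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  t0 <- ds$start_times
  t1 <- t0 + ds$window_seconds
  n <- length(t0)
  inside <- rep(FALSE, n); near <- rep(FALSE, n)
  if (nrow(seizures) > 0) for (k in seq_len(nrow(seizures))) {
    on <- seizures$onset_s[k]; off <- seizures$offset_s[k]
    inside <- inside | (t0 >= on & t1 <= off)
    near <- near | (t1 > on - guard_s & t0 < off + guard_s)
  }
  label <- ifelse(inside, 1L, ifelse(!near, 0L, NA_integer_))
  keep <- !is.na(label)
  out <- subset_windows(ds, which(keep))
  out$labels <- label[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

subset_windows <- function(ds, idx) {
  out <- ds
  out$windows <- ds$windows[idx, , , drop = FALSE]
  out$labels <- ds$labels[idx]
  out$subject_ids <- ds$subject_ids[idx]
  out$start_times <- ds$start_times[idx]
  out
}

#' Concatenate window datasets
#'
#' @param ds_list list of `window_dataset` objects with identical window
#'   geometry and sampling rate.
#' @return a single `window_dataset`.
#' @export
bind_windows <- function(ds_list) {
  stopifnot(length(ds_list) >= 1L)
  ref <- ds_list[[1]]
  for (d in ds_list[-1])
    if (d$sampling_rate != ref$sampling_rate ||
        dim(d$windows)[3] != dim(ref$windows)[3] ||
        dim(d$windows)[2] != dim(ref$windows)[2])
      stop("window datasets have inconsistent geometry")
  out <- ref
  out$windows <- do.call(abind_first, lapply(ds_list, `[[`, "windows"))
  out$labels <- unlist(lapply(ds_list, `[[`, "labels"))
  out$subject_ids <- unlist(lapply(ds_list, `[[`, "subject_ids"))
  out$start_times <- unlist(lapply(ds_list, `[[`, "start_times"))
  out$seizures <- NULL
  out
}

abind_first <- function(...) {
  arrs <- list(...)
  ns <- vapply(arrs, function(a) dim(a)[1], integer(1))
  d <- dim(arrs[[1]])
  out <- array(0, c(sum(ns), d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    if (dim(a)[1] > 0) out[(at + 1L):(at + dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Balance classes by undersampling negatives
#'
#' Per subject, randomly keeps at most `ratio` interictal windows per ictal
#' window (seeded, reproducible). All ictal windows are kept.
#'
#' @param ds a labeled `window_dataset`.
#' @param ratio interictal:ictal ratio to keep (default 1).
#' @param seed RNG seed.
#' @return a `window_dataset`.
#' @export
balance_classes <- function(ds, ratio = 1, seed = 1L) {
  stopifnot(inherits(ds, "window_dataset"), !anyNA(ds$labels))
  set.seed(as.integer(seed))
  keep <- integer(0)
  for (sid in unique(ds$subject_ids)) {
    si <- which(ds$subject_ids == sid)
    pos <- si[ds$labels[si] == 1L]
    neg <- si[ds$labels[si] == 0L]
    n_keep <- min(length(neg), ceiling(ratio * length(pos)))
    if (n_keep < length(neg)) neg <- sort(sample(neg, n_keep))
    keep <- c(keep, pos, neg)
  }
  subset_windows(ds, sort(keep))
}

#' @export
print.window_dataset <- function(x, ...) {
  d <- dim(x$windows)
  lab <- if (anyNA(x$labels)) "unlabeled"
  else sprintf("%d ictal / %d interictal", sum(x$labels == 1L), sum(x$labels == 0L))
  cat(sprintf("Window dataset: %d windows of %d ch x %d samples (%g s @ %g Hz), %s, %d subject(s)\n",
              d[1], d[2], d[3], x$window_seconds, x$sampling_rate, lab,
              length(unique(x$subject_ids))))
  invisible(x)
}

#' Save / load a window dataset
#'
#' Single-file container holding the window array, labels, subject ids,
#' start times and a provenance block (rates, geometry, package version).
#'
#' @param ds a `window_dataset`.
#' @param path file path.
#' @export
save_windows <- function(ds, path) {
  prov <- list(package_version = as.character(utils::packageVersion("cprsca")),
               sampling_rate = ds$sampling_rate,
               window_seconds = ds$window_seconds,
               channel_labels = ds$channel_labels,
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  saveRDS(list(dataset = ds, provenance = prov), path)
  invisible(path)
}

#' @rdname save_windows
#' @export
load_windows <- function(path) {
  obj <- readRDS(path)
  ds <- obj$dataset
  attr(ds, "provenance") <- obj$provenance
  ds
}

# ---- standard channel sets ---------------------------------------------

#' Standard channel sets for scalp EEG seizure detection
#'
#' `chb_mit_18_channels()`: the 18 bipolar derivations consistently present
#' across CHB-MIT cases. `montage_electrodes_15()`: the 15 monopolar 10-20
#' electrodes used for hospital recordings. `bipolar_pairs_12()`: the 12
#' bipolar derivations formed from those electrodes, following the CHB-MIT
#' convention.
#'
#' @return character vector of channel labels.
#' @export
chb_mit_18_channels <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FZ-CZ", "CZ-PZ", "FP2-F4", "F4-C4", "C4-P4", "P4-O2", "FP2-F8", "F8-T8",
    "P8-O2", "T8-P8")
}

#' @rdname chb_mit_18_channels
#' @export
montage_electrodes_15 <- function() {
  c("FP1", "F7", "F3", "C3", "P3", "O1", "FZ", "CZ", "PZ",
    "FP2", "F4", "C4", "P4", "O2", "F8")
}

#' @rdname chb_mit_18_channels
#' @export
bipolar_pairs_12 <- function() {
  c("FP1-F7", "FP1-F3", "F3-C3", "C3-P3", "P3-O1", "FZ-CZ",
    "CZ-PZ", "FP2-F4", "F4-C4", "C4-P4", "P4-O2", "FP2-F8")
}

#' Preprocess a monopolar recording into labeled windows
#'
#' The standard chain: bipolar montage, resampling to the target rate,
#' windowing, and ictal/interictal labeling with a peri-ictal guard.
#'
#' @param rec an [eeg_recording()] of monopolar electrode signals.
#' @param pairs montage pairs (default the 12 standard derivations).
#' @param target_hz target sampling rate (default 256).
#' @param window_s,stride_s window geometry in seconds.
#' @param guard_s peri-ictal guard margin for the negative class.
#' @return a labeled `window_dataset`.
#' @export
preprocess_recording <- function(rec, pairs = bipolar_pairs_12(),
                                 target_hz = 256, window_s = 3,
                                 stride_s = window_s, guard_s = 60) {
  rec <- build_bipolar_montage(rec, pairs)
  rec <- resample_recording(rec, target_hz)
  label_windows(segment_windows(rec, window_s, stride_s), guard_s = guard_s)
}

#' Preprocess a cohort of recordings into one balanced dataset
#'
#' Applies [preprocess_recording()] to each recording, balances classes
#' per subject, and concatenates.
#'
#' @param recordings list of monopolar [eeg_recording()]s.
#' @param balance_ratio interictal:ictal ratio (default 1; NULL to skip).
#' @param seed seed for the balancing undersampler.
#' @inheritParams preprocess_recording
#' @return a labeled `window_dataset` spanning all subjects.
#' @export
preprocess_cohort <- function(recordings, pairs = bipolar_pairs_12(),
                              target_hz = 256, window_s = 3,
                              stride_s = window_s, guard_s = 60,
                              balance_ratio = 1, seed = 1L) {
  ds <- bind_windows(lapply(recordings, preprocess_recording, pairs = pairs,
                            target_hz = target_hz, window_s = window_s,
                            stride_s = stride_s, guard_s = guard_s))
  if (!is.null(balance_ratio)) ds <- balance_classes(ds, balance_ratio, seed)
  ds
}
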