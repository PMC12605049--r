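#' @title Synthetic spike-and-wave EEG generator
#' @description
#' Generates multichannel EEG-like recordings with embedded seizure
#' intervals and exact ground-truth annotations, so preprocessing,
#' training and both evaluation protocols can run without any external
#' data. Background activity is 1/f^beta-coloured noise plus an
#' alpha-band rhythm, linearly mixed across electrodes; ictal segments
#' superimpose a periodic ~3 Hz spike-and-wave train at a configurable
#' amplitude ratio over background. Every output is a pure function of
#' its seeds.
#' @name synthetic_eeg
NULL

#' Per-subject generator parameters
#'
#' @param background_amp background RMS amplitude in microvolts (default 50,
#'   a typical scalp EEG scale).
#' @param pink_exponent spectral slope beta of the 1/f^beta background
#'   (default 1, classic pink noise).
#' @param alpha_freq posterior rhythm frequency in Hz (default 10).
#' @param spikewave_freq spike-and-wave repetition rate in Hz (default 3,
#'   the classic absence-seizure rate).
#' @param ictal_amp_ratio ictal-to-background amplitude multiplier (> 1;
#'   default 3).
#' @param n_electrodes electrode count (defines the mixing matrix size).
#' @param channel_mixing electrodes x sources mixing matrix; default is a
#'   dominant-diagonal matrix with mild cross-mixing, rows normalized.
#' @param seed integer RNG seed for this subject.
#' @return object of class `subject_params`.
#' @export
subject_params <- function(background_amp = 50,
                           pink_exponent = 1,
                           alpha_freq = 10,
                           spikewave_freq = 3,
                           ictal_amp_ratio = 3,
                           n_electrodes = 15L,
                           channel_mixing = NULL,
                           seed = 1L) {
  if (ictal_amp_ratio <= 1) stop("ictal_amp_ratio must exceed 1")
  if (is.null(channel_mixing)) {
    set.seed(as.integer(seed) + 7L)
    m <- diag(n_electrodes) + matrix(runif(n_electrodes^2, 0, 0.25),
                                     n_electrodes, n_electrodes)
    channel_mixing <- m / sqrt(rowSums(m^2))
  }
  structure(list(background_amp = background_amp,
                 pink_exponent = pink_exponent,
                 alpha_freq = alpha_freq,
                 spikewave_freq = spikewave_freq,
                 ictal_amp_ratio = ictal_amp_ratio,
                 n_electrodes = as.integer(n_electrodes),
                 channel_mixing = channel_mixing,
                 seed = as.integer(seed)),
            class = "subject_params")
}

#' Synthetic cohort specification
#'
#' Defaults mirror a small hospital-style acquisition: 500 Hz source rate
#' (so the resampling path is always exercised; use 256 for a
#' CHB-MIT-like preset), 15 monopolar 10-20 electrodes, a few tens of
#' seconds per seizure.
#'
#' @param n_subjects number of subjects (>= 2 so leave-one-subject-out is
#'   defined; default 5).
#' @param recording_s recording duration per subject in seconds (default 900).
#' @param seizures_per_subject embedded seizures per recording (default 3).
#' @param seizure_duration_s length-2 range of seizure durations in
#'   seconds (default 30-50).
#' @param sampling_rate acquisition rate in Hz (default 500).
#' @param electrodes electrode label set (default the 15 standard ones).
#' @param ictal_amp_ratio ictal/background amplitude ratio (default 3).
#' @param master_seed seed from which all per-subject parameters and
#'   signals derive.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 5L,
                        recording_s = 900,
                        seizures_per_subject = 3L,
                        seizure_duration_s = c(30, 50),
                        sampling_rate = 500,
                        electrodes = montage_electrodes_15(),
                        ictal_amp_ratio = 3,
                        master_seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2 (leave-one-subject-out needs at least 2)")
  tot_seizure <- seizures_per_subject * max(seizure_duration_s)
  if (tot_seizure >= recording_s)
    stop("total seizure time must be below the recording duration")
  structure(list(n_subjects = as.integer(n_subjects),
                 recording_s = recording_s,
                 seizures_per_subject = as.integer(seizures_per_subject),
                 seizure_duration_s = seizure_duration_s,
                 sampling_rate = sampling_rate,
                 electrodes = toupper(trimws(electrodes)),
                 ictal_amp_ratio = ictal_amp_ratio,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# 1/f^beta coloured noise via spectral shaping, unit RMS
pink_noise <- function(n, beta) {
  if (n < 2L) return(rnorm(max(n, 0L)))
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- f^(-beta / 2)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L) {
    full[nf + 1L] <- complex(real = amp[nf] * cos(phase[nf]))
    if (nf > 1L) full[n:(n - nf + 2L)] <- Conj(spec[1:(nf - 1L)])
  } else {
    full[n:(n - nf + 1L)] <- Conj(spec)
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate multichannel background EEG
#'
#' Per-source 1/f^beta noise plus an alpha-band sinusoid with random
#' phase, linearly mixed across electrodes and scaled to the requested
#' background RMS. Reproducible from `params$seed` (offset by `seed_offset`
#' to decorrelate multiple segments of one subject).
#'
#' @param duration_s segment duration in seconds.
#' @param params a [subject_params()].
#' @param sampling_rate sampling rate in Hz.
#' @param seed_offset integer offset added to the subject seed.
#' @return electrodes x samples matrix (microvolts).
#' @export
gen_background <- function(duration_s, params, sampling_rate = 500,
                           seed_offset = 0L) {
  n <- as.integer(round(duration_s * sampling_rate))
  E <- params$n_electrodes
  if (n == 0L) return(matrix(0, E, 0))
  set.seed(params$seed + as.integer(seed_offset))
  tt <- seq_len(n) / sampling_rate
  src <- matrix(0, E, n)
  for (e in seq_len(E)) {
    noise <- pink_noise(n, params$pink_exponent)
    alpha <- sqrt(2) * 0.4 * sin(2 * pi * params$alpha_freq * tt + runif(1, 0, 2 * pi))
    src[e, ] <- noise + alpha
  }
  mixed <- params$channel_mixing %*% src
  mixed * (params$background_amp / sqrt(rowMeans(mixed^2)))
}

# one spike-and-wave cycle template at unit peak, length = rate / f
spikewave_cycle <- function(sampling_rate, f) {
  L <- as.integer(round(sampling_rate / f))
  tt <- seq_len(L) / sampling_rate
  cyc <- numeric(L)
  # sharp biphasic spike (~70 ms): narrow positive lobe then negative lobe
  s1 <- dnorm(tt, mean = 0.030, sd = 0.008)
  s2 <- dnorm(tt, mean = 0.055, sd = 0.010)
  spike <- s1 / max(s1) - 0.6 * s2 / max(s2)
  # slow half-sine wave over ~55% of the cycle, dominant amplitude
  wave_len <- 0.55 / f
  wav <- ifelse(tt > 0.08 & tt < 0.08 + wave_len,
                sin(pi * (tt - 0.08) / wave_len), 0)
  cyc + 0.9 * spike + 1.4 * wav
}

#' Generate an ictal spike-and-wave segment
#'
#' A periodic spike-and-wave train at `params$spikewave_freq`, scaled so
#' the train's RMS is `ictal_amp_ratio` times the background RMS, with
#' background activity superimposed. The discharge is given a scalp
#' topography: per-electrode gains of varying magnitude and random
#' polarity, as generalized spike-wave fields invert across the head —
#' which also ensures differential (bipolar) derivations retain the
#' discharge instead of cancelling a spatially uniform train.
#'
#' @inheritParams gen_background
#' @return electrodes x samples matrix (microvolts).
#' @export
gen_seizure_segment <- function(duration_s, params, sampling_rate = 500,
                                seed_offset = 1000L) {
  n <- as.integer(round(duration_s * sampling_rate))
  E <- params$n_electrodes
  if (n == 0L) return(matrix(0, E, 0))
  bg <- gen_background(duration_s, params, sampling_rate, seed_offset)
  set.seed(params$seed + as.integer(seed_offset) + 1L)
  cyc <- spikewave_cycle(sampling_rate, params$spikewave_freq)
  train <- rep_len(cyc, n)
  train <- train / sqrt(mean(train^2))
  gains <- sample(c(-1, 1), E, replace = TRUE) * runif(E, 0.6, 1.4)
  amp <- params$background_amp * params$ictal_amp_ratio
  sw <- outer(gains, train) * amp
  sw + bg
}

#' Generate one subject's recording with embedded seizures
#'
#' Seizure start times are drawn uniformly, rejected until non-overlapping
#' with a minimum 20 s separation, and spliced into the background with a
#' 0.5 s linear cross-fade. Annotations exactly match the splice
#' intervals.
#'
#' @param spec a [cohort_spec()].
#' @param subject_idx subject index in `1:spec$n_subjects`.
#' @return an [eeg_recording()] with ground-truth seizure annotations.
#' @export
gen_recording <- function(spec, subject_idx) {
  pars <- cohort_subject_params(spec)[[subject_idx]]
  fs <- spec$sampling_rate
  dur <- spec$recording_s
  sig <- gen_background(dur, pars, fs, seed_offset = 0L)

  set.seed(pars$seed + 5000L)
  k <- spec$seizures_per_subject
  lens <- runif(k, spec$seizure_duration_s[1], spec$seizure_duration_s[2])
  starts <- numeric(0)
  margin <- 20
  tries <- 0L
  while (length(starts) < k) {
    cand <- runif(1, margin, dur - max(lens) - margin)
    ok <- all(abs(cand - starts) > max(lens) + margin)
    if (ok) starts <- c(starts, cand)
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place non-overlapping seizures; lower seizures_per_subject or lengthen recording_s")
  }
  ord <- order(starts)
  starts <- starts[ord]; lens <- lens[ord]

  fade_n <- as.integer(round(0.5 * fs))
  seizures <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  for (j in seq_len(k)) {
    i0 <- as.integer(round(starts[j] * fs))
    seg <- gen_seizure_segment(lens[j], pars, fs, seed_offset = 1000L * j)
    nseg <- ncol(seg)
    idx <- (i0 + 1L):(i0 + nseg)
    ramp <- rep(1, nseg)
    ramp[seq_len(fade_n)] <- seq(0, 1, length.out = fade_n)
    ramp[(nseg - fade_n + 1L):nseg] <- seq(1, 0, length.out = fade_n)
    mix <- matrix(ramp, nrow(sig), nseg, byrow = TRUE)
    sig[, idx] <- (1 - mix) * sig[, idx] + mix * seg
    seizures <- rbind(seizures,
                      data.frame(onset_s = i0 / fs, offset_s = (i0 + nseg) / fs))
  }
  eeg_recording(sprintf("S%02d", subject_idx), spec$electrodes, fs, sig, seizures)
}

# draw per-subject parameter jitter deterministically from the master seed
cohort_subject_params <- function(spec) {
  set.seed(spec$master_seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, spec$n_subjects)
  amps <- exp(rnorm(spec$n_subjects, log(50), 0.2))
  alphas <- runif(spec$n_subjects, 8, 12)
  betas <- rnorm(spec$n_subjects, 1, 0.1)
  lapply(seq_len(spec$n_subjects), function(i)
    subject_params(background_amp = amps[i],
                   pink_exponent = betas[i],
                   alpha_freq = alphas[i],
                   ictal_amp_ratio = spec$ictal_amp_ratio,
                   n_electrodes = length(spec$electrodes),
                   seed = seeds[i]))
}

#' Generate a synthetic cohort
#'
#' One recording per subject, with inter-subject jitter in background
#' amplitude, spectral slope, alpha frequency and channel mixing so that
#' leave-one-subject-out evaluation is non-degenerate. Regeneration from
#' the same `master_seed` is bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @return list of [eeg_recording()]s with distinct subject ids.
#' @export
gen_cohort <- function(spec) {
  lapply(seq_len(spec$n_subjects), function(i) gen_recording(spec, i))
}
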