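#' Configuration for a synthetic EEG cohort
#'
#' Describes one cohort of simulated routine EEG registrations. The simulated
#' signals are not biophysical EEG: each recording is 1/f-shaped Gaussian
#' background noise, scaled by a per-patient amplitude factor (lognormal,
#' `baseline_offset_sd` on the log scale) and shaped by a per-patient spectral
#' slope, with seizures superimposed as amplitude-ramped rhythmic discharges.
#' These are exactly the statistical ingredients the detection pipeline
#' assumes: rhythmic seizure activity against coloured background, plus
#' inter-patient baseline differences that feature baseline correction (FBC)
#' must compensate.
#'
#' @param cohort_name cohort label; also the patient-id namespace.
#' @param n_patients number of patients (>= 2).
#' @param n_channels number of EEG channels (9 emulates a reduced neonatal
#'   montage, 19 the full 10-20 adult montage).
#' @param sample_rate_hz generation-time sampling rate in Hz.
#' @param duration_s recording duration in seconds (>= 180 so a seizure-free
#'   baseline window always exists).
#' @param seizure_rate expected seizures per recording (>= 1); the realised
#'   count is `1 + Poisson(seizure_rate - 1)` so every recording contains at
#'   least one seizure.
#' @param seizure_duration_s length-2 vector, min/max seizure duration (s).
#' @param seizure_freq_hz length-2 vector, min/max dominant rhythm frequency.
#' @param baseline_offset_sd sd (log scale) of the per-patient multiplicative
#'   amplitude factor; 0 disables inter-patient baseline shifts.
#' @param spectral_offset_sd sd of the per-patient jitter on the background
#'   spectral slope; 0 disables inter-patient spectral shifts.
#' @param background_spectral_slope exponent of the 1/f^slope background.
#' @param seizure_harmonic add a second harmonic to the seizure rhythm
#'   (more complex, neonatal-like waveforms).
#' @param prob_focal probability that a seizure is focal (confined to a random
#'   half of the channels) rather than generalized.
#' @param background_rms_uv background RMS amplitude in microvolts before the
#'   patient factor is applied.
#' @param seizure_amp_uv seizure rhythm amplitude in microvolts (scaled by the
#'   same patient factor as the background).
#' @param seed integer seed; generation is a pure function of (config, seed).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(cohort_name,
                          n_patients,
                          n_channels,
                          sample_rate_hz = 250,
                          duration_s = 1200,
                          seizure_rate = 2,
                          seizure_duration_s = c(30, 120),
                          seizure_freq_hz = c(1, 4),
                          baseline_offset_sd = 0.4,
                          spectral_offset_sd = 0.25,
                          background_spectral_slope = 1,
                          seizure_harmonic = FALSE,
                          prob_focal = 0.3,
                          background_rms_uv = 20,
                          seizure_amp_uv = 30,
                          seed = 1L) {
  stopifnot(
    is.character(cohort_name), nchar(cohort_name) > 0,
    n_patients >= 2,
    n_channels >= 1,
    sample_rate_hz > 0,
    duration_s >= 180,
    seizure_rate >= 1,
    length(seizure_duration_s) == 2, all(seizure_duration_s > 0),
    seizure_duration_s[1] <= seizure_duration_s[2],
    length(seizure_freq_hz) == 2, all(seizure_freq_hz > 0),
    seizure_freq_hz[1] <= seizure_freq_hz[2],
    baseline_offset_sd >= 0, spectral_offset_sd >= 0,
    prob_focal >= 0, prob_focal <= 1
  )
  if (duration_s - 180 < seizure_duration_s[1]) {
    stop("duration_s too short to place a seizure after the 180 s baseline window")
  }
  structure(list(
    cohort_name = cohort_name, n_patients = as.integer(n_patients),
    n_channels = as.integer(n_channels), sample_rate_hz = sample_rate_hz,
    duration_s = duration_s, seizure_rate = seizure_rate,
    seizure_duration_s = seizure_duration_s, seizure_freq_hz = seizure_freq_hz,
    baseline_offset_sd = baseline_offset_sd,
    spectral_offset_sd = spectral_offset_sd,
    background_spectral_slope = background_spectral_slope,
    seizure_harmonic = seizure_harmonic, prob_focal = prob_focal,
    background_rms_uv = background_rms_uv, seizure_amp_uv = seizure_amp_uv,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Preset: neonatal-like cohort (9-channel reduced montage)
#'
#' Slow (1-3.5 Hz) seizure rhythm with a second harmonic, emulating the more
#' complex discharge morphology of the immature brain.
#'
#' @param n_patients,seed,... passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
neonatal_cohort_config <- function(n_patients = 5, seed = 1L, ...) {
  cohort_config("neo", n_patients = n_patients, n_channels = 9,
                seizure_freq_hz = c(1, 3.5), seizure_harmonic = TRUE,
                seed = seed, ...)
}

#' Preset: adult-like cohort (19-channel full 10-20 montage)
#'
#' @param n_patients,seed,... passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
adult_cohort_config <- function(n_patients = 5, seed = 2L, ...) {
  cohort_config("adult", n_patients = n_patients, n_channels = 19,
                seizure_freq_hz = c(3, 6), seizure_harmonic = FALSE,
                seed = seed, ...)
}

channel_labels <- function(n) {
  if (n == 9) {
    c("Fp1", "Fp2", "C3", "C4", "Cz", "T3", "T4", "O1", "O2")
  } else if (n == 19) {
    c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
      "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  } else {
    sprintf("Ch%02d", seq_len(n))
  }
}

# 1/f^slope coloured Gaussian noise via spectral shaping, unit RMS
colored_noise <- function(n, fs, slope) {
  w <- stats::rnorm(n)
  if (slope == 0) return(w / stats::sd(w))
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  scale <- ifelse(f > 0, f^(-slope / 2), 0)
  x <- Re(stats::fft(X * scale, inverse = TRUE) / n)
  x / stats::sd(x)
}

# per-patient latent factors, drawn once per patient from the patient seed
patient_factors <- function(config, patient_index) {
  ps <- derive_seed(config$seed, patient_index)
  with_seed(ps, {
    amp <- exp(stats::rnorm(1, 0, config$baseline_offset_sd))
    slope <- config$background_spectral_slope +
      stats::rnorm(1, 0, config$spectral_offset_sd)
    list(amp = amp, slope = max(slope, 0.2))
  })
}

#' Generate one annotated synthetic EEG recording
#'
#' Deterministic given `(config$seed, patient_index, record_index)`. The first
#' 180 s are kept seizure-free by construction so that a clean baseline window
#' for FBC always exists.
#'
#' @param config a [cohort_config()].
#' @param patient_index 1-based patient index within the cohort.
#' @param record_index 1-based recording index for that patient.
#' @return an object of class `eeg_recording`: list with `patient_id`,
#'   `record_id`, `cohort`, `channels`, `signal` (channels x samples matrix,
#'   microvolts), `sample_rate_hz`, `duration_s` and `annotations`
#'   (data.frame with `start_s`, `end_s`; half-open intervals).
#' @export
generate_recording <- function(config, patient_index, record_index = 1L) {
  stopifnot(inherits(config, "cohort_config"),
            patient_index >= 1, patient_index <= config$n_patients,
            record_index >= 1)
  pf <- patient_factors(config, patient_index)
  fs <- config$sample_rate_hz
  n <- round(config$duration_s * fs)
  rec_seed <- derive_seed(derive_seed(config$seed, patient_index),
                          100000 + record_index)
  with_seed(rec_seed, {
    nch <- config$n_channels
    sig <- matrix(0, nrow = nch, ncol = n)
    for (ch in seq_len(nch)) {
      sig[ch, ] <- colored_noise(n, fs, pf$slope) *
        config$background_rms_uv * pf$amp
    }

    n_seiz <- 1L + stats::rpois(1, max(config$seizure_rate - 1, 0))
    # sequential placement in the post-baseline window with 10 s guard bands:
    # draw durations, shrink the count until the set fits, then distribute the
    # remaining slack as random gaps
    window_len <- config$duration_s - 180
    durs <- numeric(0)
    while (n_seiz >= 1) {
      durs <- stats::runif(n_seiz, config$seizure_duration_s[1],
                           config$seizure_duration_s[2])
      if (n_seiz == 1) durs <- min(durs, window_len)
      if (sum(durs) + 10 * (n_seiz - 1) <= window_len) break
      n_seiz <- n_seiz - 1L
    }
    if (n_seiz < 1 || durs[1] < config$seizure_duration_s[1] - 1e-9) {
      stop("duration_s too short to place the requested seizures")
    }
    slack <- window_len - sum(durs) - 10 * (n_seiz - 1)
    gaps <- stats::runif(n_seiz + 1)
    gaps <- gaps / sum(gaps) * slack
    onsets <- 180 + cumsum(gaps[seq_len(n_seiz)]) +
      c(0, cumsum(durs[-n_seiz] + 10))
    placed <- data.frame(start_s = onsets, end_s = onsets + durs)

    t_all <- (seq_len(n) - 1) / fs
    for (i in seq_len(nrow(placed))) {
      i0 <- floor(placed$start_s[i] * fs) + 1
      i1 <- min(ceiling(placed$end_s[i] * fs), n)
      idx <- i0:i1
      tt <- t_all[idx] - placed$start_s[i]
      dur <- placed$end_s[i] - placed$start_s[i]
      # trapezoidal amplitude envelope: 20% ramp up / 20% ramp down
      env <- pmin(1, pmin(tt, dur - tt) / (0.2 * dur))
      env <- pmax(env, 0)
      f0 <- stats::runif(1, config$seizure_freq_hz[1], config$seizure_freq_hz[2])
      ph <- stats::runif(2, 0, 2 * pi)
      amp <- config$seizure_amp_uv * pf$amp
      wave <- amp * env * sin(2 * pi * f0 * tt + ph[1])
      if (config$seizure_harmonic) {
        wave <- wave + 0.4 * amp * env * sin(2 * pi * 2 * f0 * tt + ph[2])
      }
      focal <- stats::runif(1) < config$prob_focal
      chans <- if (focal) {
        sort(sample.int(config$n_channels, ceiling(config$n_channels / 2)))
      } else {
        seq_len(config$n_channels)
      }
      for (ch in chans) sig[ch, idx] <- sig[ch, idx] + wave
    }

    structure(list(
      patient_id = sprintf("%s_P%02d", config$cohort_name, patient_index),
      record_id = sprintf("%s_P%02d_R%02d", config$cohort_name,
                          patient_index, record_index),
      cohort = config$cohort_name,
      channels = channel_labels(config$n_channels),
      signal = sig,
      sample_rate_hz = fs,
      duration_s = config$duration_s,
      annotations = placed
    ), class = "eeg_recording")
  })
}

#' Generate a full synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param records_per_patient recordings per patient (>= 1).
#' @return list of `eeg_recording` objects.
#' @export
generate_cohort <- function(config, records_per_patient = 1L) {
  stopifnot(records_per_patient >= 1)
  recs <- list()
  for (p in seq_len(config$n_patients)) {
    for (r in seq_len(records_per_patient)) {
      recs[[length(recs) + 1L]] <- generate_recording(config, p, r)
    }
  }
  recs
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s): %d ch x %.0f s @ %g Hz, %d seizure(s)\n",
              x$record_id, x$cohort, nrow(x$signal), x$duration_s,
              x$sample_rate_hz, nrow(x$annotations)))
  invisible(x)
}
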