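#' Zero-phase band-pass filter an EEG recording
#'
#' 4th-order Butterworth applied forward-backward (zero phase) per channel.
#' Default band 0.5-32 Hz, the conventional band for routine seizure review.
#'
#' @param recording an `eeg_recording`.
#' @param low_hz,high_hz band edges in Hz; `0 < low < high < fs/2` required.
#' @param order Butterworth order (per pass).
#' @return the filtered `eeg_recording` (sample rate unchanged).
#' @export
eeg_bandpass <- function(recording, low_hz = 0.5, high_hz = 32, order = 4) {
  fs <- recording$sample_rate_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("invalid band: need 0 < low_hz < high_hz < fs/2")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- recording
  for (ch in seq_len(nrow(out$signal))) {
    # demean first: the DC offset is outside the passband anyway, and removing
    # it avoids the step-response transient of the forward-backward pass
    x <- recording$signal[ch, ]
    out$signal[ch, ] <- signal::filtfilt(bf, x - mean(x))
  }
  out
}

#' Resample (down-sample) an EEG recording
#'
#' Applies a zero-phase anti-alias low-pass at `0.45 * target_hz` before
#' decimation. A band-pass whose upper edge exceeds the target Nyquist (e.g.
#' 32 Hz followed by 25 Hz sampling) would otherwise alias; the anti-alias
#' stage can be disabled to reproduce plain decimation.
#'
#' @param recording an `eeg_recording`.
#' @param target_hz target sampling rate; must not exceed the current rate.
#' @param anti_alias apply the anti-alias low-pass (default TRUE).
#' @return the resampled `eeg_recording`; annotations (in seconds) unchanged.
#' @export
eeg_resample <- function(recording, target_hz = 25, anti_alias = TRUE) {
  fs <- recording$sample_rate_hz
  if (target_hz > fs) stop("upsampling not supported (target_hz > sample rate)")
  if (abs(target_hz - fs) < 1e-12) return(recording)
  out <- recording
  sig <- recording$signal
  if (anti_alias) {
    lp <- signal::butter(4, (0.45 * target_hz) / (fs / 2), type = "low")
    for (ch in seq_len(nrow(sig))) {
      sig[ch, ] <- signal::filtfilt(lp, sig[ch, ])
    }
  }
  ratio <- fs / target_hz
  n_new <- floor(ncol(sig) * target_hz / fs)
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, by = round(ratio), length.out = n_new)
    sig <- sig[, idx, drop = FALSE]
  } else {
    t_old <- (seq_len(ncol(sig)) - 1) / fs
    t_new <- (seq_len(n_new) - 1) / target_hz
    sig <- t(apply(sig, 1, function(x) {
      stats::approx(t_old, x, xout = t_new, rule = 2)$y
    }))
  }
  out$signal <- sig
  out$sample_rate_hz <- target_hz
  out$duration_s <- n_new / target_hz
  out
}

#' Partition a recording into overlapping epochs
#'
#' Default 10-s epochs with 5-s stride (50% overlap). Epochs are half-open
#' `[start, start + epoch_length)` in seconds and must lie fully inside the
#' recording.
#'
#' @param recording an `eeg_recording` (or anything with `duration_s`).
#' @param epoch_length_s epoch length in seconds.
#' @param stride_s stride between epoch starts in seconds
#'   (`stride_s <= epoch_length_s`).
#' @return an `epoch_grid`: list with `epoch_length_s`, `stride_s`,
#'   `epoch_starts_s`, `n_epochs`.
#' @export
make_epochs <- function(recording, epoch_length_s = 10, stride_s = 5) {
  stopifnot(stride_s > 0, stride_s <= epoch_length_s)
  duration <- recording$duration_s
  if (duration < epoch_length_s) {
    stop("recording shorter than one epoch (", duration, " < ",
         epoch_length_s, " s)")
  }
  n_epochs <- floor((duration - epoch_length_s) / stride_s + 1e-9) + 1
  structure(list(
    epoch_length_s = epoch_length_s,
    stride_s = stride_s,
    epoch_starts_s = (seq_len(n_epochs) - 1) * stride_s,
    n_epochs = as.integer(n_epochs)
  ), class = "epoch_grid")
}

#' Label epochs as seizure / non-seizure from interval annotations
#'
#' An epoch is labelled seizure (1) iff its overlap with the union of the
#' annotated seizure intervals is at least `overlap_fraction * epoch_length`
#' (inclusive).
#'
#' @param grid an `epoch_grid`.
#' @param annotations data.frame with `start_s`, `end_s`.
#' @param overlap_fraction rule in (0, 1]; default 0.5.
#' @return integer vector of 0/1 labels, one per epoch.
#' @export
label_epochs <- function(grid, annotations, overlap_fraction = 0.5) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1)
  merged <- merge_intervals(annotations)
  need <- overlap_fraction * grid$epoch_length_s
  vapply(grid$epoch_starts_s, function(s) {
    ov <- interval_overlap(s, s + grid$epoch_length_s, merged)
    as.integer(ov >= need - 1e-9)
  }, integer(1))
}

#' Standard preprocessing chain: band-pass, down-sample, epoch
#'
#' Fixed order filter -> resample -> epoch.
#'
#' @param recording an `eeg_recording`.
#' @param low_hz,high_hz band-pass edges (Hz).
#' @param target_hz working sampling rate after down-sampling.
#' @param epoch_length_s,stride_s epoch grid parameters.
#' @param anti_alias see [eeg_resample()].
#' @return list with elements `recording` (preprocessed) and `grid`.
#' @export
preprocess_recording <- function(recording, low_hz = 0.5, high_hz = 32,
                                 target_hz = 25, epoch_length_s = 10,
                                 stride_s = 5, anti_alias = TRUE) {
  rec <- eeg_bandpass(recording, low_hz, high_hz)
  rec <- eeg_resample(rec, target_hz, anti_alias = anti_alias)
  grid <- make_epochs(rec, epoch_length_s, stride_s)
  list(recording = rec, grid = grid)
}
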