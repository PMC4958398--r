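#' Write an EEG recording to an EDF file
#'
#' Minimal European Data Format (EDF) writer: 256-byte fixed header plus one
#' 256-byte header block per signal, 16-bit little-endian samples, 1-second
#' data records. Seizure annotations are NOT embedded (plain EDF has no
#' annotation channel); use [write_annotations()] for the CSV sidecar.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  sig <- recording$signal
  fs <- recording$sample_rate_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sample rate")
  fs <- as.integer(round(fs))
  n_rec <- floor(ncol(sig) / fs)
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  ns <- nrow(sig)

  pmax_ <- max(1, ceiling(max(abs(sig), na.rm = TRUE)))
  dig_max <- 32767L
  # digital <-> physical scaling (symmetric range)
  scale <- dig_max / pmax_

  pad <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    sprintf("%-*s", width, x)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(recording$patient_id %||% "X", 80),
    pad(recording$record_id %||% "recording", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8),
    pad("", 44),
    pad(n_rec, 8),
    pad("1", 8),
    pad(ns, 4)
  )
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  fields <- list(
    list(recording$channels, 16),
    list(rep("synthetic EEG", ns), 80),
    list(rep("uV", ns), 8),
    list(rep(format(-pmax_), ns), 8),
    list(rep(format(pmax_), ns), 8),
    list(rep("-32767", ns), 8),
    list(rep("32767", ns), 8),
    list(rep("", ns), 80),
    list(rep(as.character(fs), ns), 8),
    list(rep("", ns), 32)
  )
  for (f in fields) {
    s <- paste0(vapply(f[[1]], pad, "", width = f[[2]]), collapse = "")
    writeChar(s, con, nchars = nchar(s), eos = NULL)
  }
  dig <- round(sig * scale)
  dig[dig > dig_max] <- dig_max
  dig[dig < -dig_max] <- -dig_max
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- as.integer(t(dig[, cols, drop = FALSE]))
    writeBin(block, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an `eeg_recording`
#'
#' Counterpart of [write_edf()]. All signals must share one sampling rate.
#' Annotations are not read from the EDF; attach them from the CSV sidecar
#' (see [read_annotations()]).
#'
#' @param path EDF file path.
#' @param annotations optional data.frame with `start_s`, `end_s` to attach.
#' @return an `eeg_recording` (cohort set to `NA` unless recoverable).
#' @export
read_edf <- function(path, annotations = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    raw <- readChar(con, nc, useBytes = TRUE)
    trimws(raw)
  }
  rd(8)                                  # version
  patient_id <- rd(80)
  record_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # phys dim
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = ns * spr[1], size = 2,
                     endian = "little")
    m <- matrix(block, nrow = spr[1], ncol = ns)
    for (i in seq_len(ns)) {
      g <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      sig[i, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (m[, i] - dmin_[i]) * g + pmin_[i]
    }
  }
  ann <- if (is.null(annotations)) {
    data.frame(start_s = numeric(0), end_s = numeric(0))
  } else {
    annotations[, c("start_s", "end_s"), drop = FALSE]
  }
  structure(list(
    patient_id = patient_id, record_id = record_id, cohort = NA_character_,
    channels = labels, signal = sig, sample_rate_hz = fs,
    duration_s = ncol(sig) / fs, annotations = ann
  ), class = "eeg_recording")
}

#' Write / read the seizure-annotation sidecar CSV
#'
#' One row per seizure interval, columns `patient_id`, `record_id`,
#' `start_s`, `end_s` (half-open `[start_s, end_s)` in seconds).
#'
#' @param recordings list of `eeg_recording` objects.
#' @param path CSV path.
#' @return `path` invisibly (`write_annotations`); a data.frame
#'   (`read_annotations`).
#' @export
write_annotations <- function(recordings, path) {
  rows <- lapply(recordings, function(r) {
    if (nrow(r$annotations) == 0) return(NULL)
    data.frame(patient_id = r$patient_id, record_id = r$record_id,
               start_s = r$annotations$start_s, end_s = r$annotations$end_s)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(patient_id = character(0), record_id = character(0),
                     start_s = numeric(0), end_s = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
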