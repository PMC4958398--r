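#' The versioned manifest of the 103 quantitative EEG features
#'
#' One row per feature, in the fixed extraction order. The `scaling` column
#' records how each feature responds to multiplying the input epoch by k > 0:
#' `"power"` scales by k^2, `"amplitude"` by k, `"invariant"` is unchanged,
#' `"other"` is affine in log k (the 0th cepstral coefficient).
#'
#' Battery composition (counts to exactly 103):
#' total power 0-12 Hz (1); spectral peak frequency (1); spectral edge
#' frequency at 80/90/95% (3); power in 11 overlapping 2-Hz subbands
#' 0-2 ... 10-12 Hz (11); the same subbands normalized by total power (11);
#' Db4 wavelet detail energies at the two scales bracketing 1-2 Hz (2);
#' curve length (1); number of local maxima and of local minima (2); RMS
#' amplitude (1); Hjorth activity/mobility/complexity (3); zero-crossing rate
#' of the signal and of its first and second differences (3); variance of the
#' first and second differences (2); autoregressive modelling error for model
#' orders 1-9 (9); skewness and kurtosis (2); nonlinear (Teager) energy (1);
#' Shannon, spectral and SVD entropy (3); Fisher information (1); linear
#' filter-bank energies in 15 subbands 0-2 ... 14-16 Hz (15); 15 cepstral
#' coefficients (15); 15 frequency-filtered bank energies (15); peak-to-peak
#' voltage (1).
#'
#' @return data.frame with columns `index`, `name`, `group`, `scaling`;
#'   attribute `version`.
#' @export
feature_manifest <- function() {
  if (!is.null(.manifest_cache$m)) return(.manifest_cache$m)
  row <- function(name, group, scaling) {
    data.frame(name = name, group = group, scaling = scaling,
               stringsAsFactors = FALSE)
  }
  sub_lo <- 0:10                       # 11 overlapping 2-Hz subbands
  fb_lo <- 0:14                        # 15 filter-bank subbands
  m <- rbind(
    row("total_power_0_12", "spectral", "power"),
    row("peak_freq", "spectral", "invariant"),
    row("sef_80", "spectral", "invariant"),
    row("sef_90", "spectral", "invariant"),
    row("sef_95", "spectral", "invariant"),
    do.call(rbind, lapply(sub_lo, function(lo)
      row(sprintf("bp_%d_%d", lo, lo + 2), "spectral", "power"))),
    do.call(rbind, lapply(sub_lo, function(lo)
      row(sprintf("nbp_%d_%d", lo, lo + 2), "spectral", "invariant"))),
    row("wavelet_d3", "wavelet", "power"),
    row("wavelet_d4", "wavelet", "power"),
    row("curve_length", "time", "amplitude"),
    row("n_maxima", "time", "invariant"),
    row("n_minima", "time", "invariant"),
    row("rms", "time", "amplitude"),
    row("hjorth_activity", "time", "power"),
    row("hjorth_mobility", "time", "invariant"),
    row("hjorth_complexity", "time", "invariant"),
    row("zcr", "time", "invariant"),
    row("zcr_d1", "time", "invariant"),
    row("zcr_d2", "time", "invariant"),
    row("var_d1", "time", "power"),
    row("var_d2", "time", "power"),
    do.call(rbind, lapply(1:9, function(k)
      row(sprintf("ar_err_%d", k), "model", "power"))),
    row("skewness", "statistical", "invariant"),
    row("kurtosis", "statistical", "invariant"),
    row("teager_energy", "time", "power"),
    row("shannon_entropy", "information", "invariant"),
    row("spectral_entropy", "information", "invariant"),
    row("svd_entropy", "information", "invariant"),
    row("fisher_information", "information", "invariant"),
    do.call(rbind, lapply(fb_lo, function(lo)
      row(sprintf("fb_%d_%d", lo, lo + 2), "filterbank", "power"))),
    row("cepstral_1", "cepstral", "other"),
    do.call(rbind, lapply(2:15, function(k)
      row(sprintf("cepstral_%d", k), "cepstral", "invariant"))),
    do.call(rbind, lapply(1:15, function(k)
      # edge terms difference against the zero padding, so they shift with
      # overall amplitude; interior differences are scale-invariant
      row(sprintf("ff_%d", k), "freqfiltered",
          if (k %in% c(1, 15)) "other" else "invariant"))),
    row("pp_voltage", "time", "amplitude")
  )
  m <- cbind(index = seq_len(nrow(m)), m)
  stopifnot(nrow(m) == 103L, !anyDuplicated(m$name))
  attr(m, "version") <- "1.0"
  .manifest_cache$m <- m
  m
}

.manifest_cache <- new.env(parent = emptyenv())

# ---- spectral helpers -------------------------------------------------------

#' Welch power spectral density estimate
#'
#' Hamming-windowed, mean-removed segments with 50% overlap (default 2-s
#' segments), averaged one-sided periodograms. Density scaling: the integral
#' of `psd * df` over frequency equals the windowed signal power.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds.
#' @return list with `freq` and `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 2) {
  n <- length(x)
  m <- min(n, round(window_s * fs))
  step <- max(1, floor(m / 2))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(m - 1)) / (m - 1))
  U <- sum(w^2)
  starts <- seq(1, n - m + 1, by = step)
  nfreq <- floor(m / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + m - 1)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg))^2 / (fs * U)
    p1 <- P[seq_len(nfreq)]
    # one-sided doubling (not DC; not Nyquist when m even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (m %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p1 * dbl
  }
  list(freq = (seq_len(nfreq) - 1) * fs / m, psd = acc / length(starts))
}

# integrated PSD power over half-open band [lo, hi)
band_power <- function(freq, psd, lo, hi) {
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  sum(psd[freq >= lo - 1e-9 & freq < hi - 1e-9]) * df
}

# spectral edge frequency: smallest f with cumulative power >= p * total,
# over the 0-12 Hz analysis band
spectral_edge <- function(freq, psd, p, f_hi = 12) {
  keep <- freq < f_hi - 1e-9
  f <- freq[keep]
  cp <- cumsum(psd[keep])
  tot <- cp[length(cp)]
  if (tot <= 0) return(0)
  f[which(cp >= p * tot)[1]]
}

# ---- Db4 wavelet ------------------------------------------------------------

# Daubechies-4 (8-tap) decomposition filters
db4_filters <- function() {
  h <- c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
         -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
         0.7148465705525415, 0.23037781330885523)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(lo = h, hi = g)
}

# one periodized DWT analysis step -> list(approx, detail)
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2 == 1) {
    x <- c(x, x[1])
    n <- n + 1
  }
  L <- length(lo)
  xe <- c(x, x[seq_len(L - 1)])           # periodic extension
  E <- stats::embed(xe, L)                # E[i, ] = xe[i+L-1], ..., xe[i]
  E <- E[seq(1, n, by = 2), , drop = FALSE]
  list(a = drop(E %*% rev(lo)), d = drop(E %*% rev(hi)))
}

#' Db4 wavelet detail energies
#'
#' Periodized Daubechies-4 pyramid; returns the detail-coefficient energies
#' (sum of squares) per level. At a 25 Hz working rate the detail levels 3 and
#' 4 cover approximately 1.56-3.13 Hz and 0.78-1.56 Hz, the two scales
#' bracketing the 1-2 Hz seizure rhythm band.
#'
#' @param x numeric vector.
#' @param levels number of decomposition levels.
#' @return numeric vector of detail energies, level 1 (highest frequency)
#'   first.
#' @export
db4_detail_energies <- function(x, levels = 4) {
  f <- db4_filters()
  en <- numeric(levels)
  a <- x
  for (l in seq_len(levels)) {
    st <- dwt_step(a, f$lo, f$hi)
    en[l] <- sum(st$d^2)
    a <- st$a
  }
  en
}

# ---- small time-domain helpers ---------------------------------------------

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0)
}

count_local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(c(0, 0))
  core <- x[2:(n - 1)]
  up <- core > x[1:(n - 2)] & core > x[3:n]
  dn <- core < x[1:(n - 2)] & core < x[3:n]
  c(sum(up), sum(dn))
}

# Burg AR residual variances for orders 1..max_order, monotone by construction
ar_burg_errors <- function(x, max_order = 9) {
  v0 <- mean((x - mean(x))^2)
  if (v0 <= .Machine$double.eps) return(numeric(max_order))
  fit <- tryCatch(
    stats::ar.burg(x, aic = FALSE, order.max = max_order, demean = TRUE),
    error = function(e) NULL
  )
  if (is.null(fit)) return(numeric(max_order))
  k <- as.numeric(fit$partialacf)
  errs <- numeric(max_order)
  v <- v0
  for (i in seq_len(max_order)) {
    v <- v * (1 - k[i]^2)
    errs[i] <- v
  }
  errs
}

shannon_entropy_hist <- function(x, n_bins = 16) {
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps) return(0)
  cuts <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log(p))
}

svd_spectrum <- function(x, dim = 20, delay = 1) {
  n <- length(x)
  rows <- n - (dim - 1) * delay
  if (rows < dim) {
    dim <- max(2, floor(n / 2))
    rows <- n - (dim - 1) * delay
  }
  Y <- matrix(0, nrow = rows, ncol = dim)
  for (j in seq_len(dim)) Y[, j] <- x[(1 + (j - 1) * delay):(rows + (j - 1) * delay)]
  d <- svd(Y, nu = 0, nv = 0)$d
  if (sum(d) <= .Machine$double.eps) return(NULL)
  d / sum(d)
}

# DCT-II (orthonormality not needed; fixed linear map of the log energies)
dct2 <- function(e) {
  N <- length(e)
  vapply(0:(N - 1), function(k) {
    sum(e * cos(pi * k * ((seq_len(N)) - 0.5) / N))
  }, 0)
}

# ---- main extractor ---------------------------------------------------------

#' Extract the 103-feature vector from one epoch of one channel
#'
#' The input is a single epoch at the working sampling rate (250 samples for
#' the default 10 s at 25 Hz). Degenerate (constant) epochs yield defined
#' fallbacks — entropies, skewness, kurtosis, mobility and peak frequency are
#' 0 — never NaN/Inf.
#'
#' @param x numeric vector, one epoch of one channel (microvolts).
#' @param fs working sampling rate in Hz.
#' @param epoch_length_s expected epoch length in seconds; the input must have
#'   exactly `round(epoch_length_s * fs)` samples.
#' @return named numeric vector of length 103 in [feature_manifest()] order.
#' @export
extract_features <- function(x, fs = 25, epoch_length_s = 10) {
  n_exp <- round(epoch_length_s * fs)
  if (length(x) != n_exp) {
    stop("epoch has ", length(x), " samples; expected ", n_exp)
  }
  if (anyNA(x) || any(!is.finite(x))) stop("epoch contains non-finite values")

  sp <- welch_psd(x, fs, window_s = 2)
  freq <- sp$freq
  psd <- sp$psd

  total_power <- band_power(freq, psd, 0, 12)
  peak_freq <- if (sum(psd) <= .Machine$double.eps) 0 else freq[which.max(psd)]
  sef <- vapply(c(0.80, 0.90, 0.95), function(p) spectral_edge(freq, psd, p), 0)

  sub_lo <- 0:10
  bp <- vapply(sub_lo, function(lo) band_power(freq, psd, lo, lo + 2), 0)
  nbp <- if (total_power > 0) bp / total_power else rep(0, length(bp))

  wav <- db4_detail_energies(x, levels = 4)
  wavelet_d3 <- wav[3]
  wavelet_d4 <- wav[4]

  dx <- diff(x)
  ddx <- diff(dx)
  curve_length <- sum(abs(dx))
  extrema <- count_local_extrema(x)
  rms <- sqrt(mean(x^2))

  v0 <- mean((x - mean(x))^2)
  v1 <- if (length(dx) > 0) mean((dx - mean(dx))^2) else 0
  v2 <- if (length(ddx) > 0) mean((ddx - mean(ddx))^2) else 0
  mobility <- if (v0 > 0) sqrt(v1 / v0) else 0
  mob_d <- if (v1 > 0) sqrt(v2 / v1) else 0
  complexity <- if (mobility > 0) mob_d / mobility else 0

  zcr <- zero_crossings(x)
  zcr1 <- zero_crossings(dx)
  zcr2 <- zero_crossings(ddx)
  var_d1 <- if (length(dx) > 1) stats::var(dx) else 0
  var_d2 <- if (length(ddx) > 1) stats::var(ddx) else 0

  ar_err <- ar_burg_errors(x, 9)

  skw <- if (v0 > 0) mean((x - mean(x))^3) / v0^1.5 else 0
  krt <- if (v0 > 0) mean((x - mean(x))^4) / v0^2 - 3 else 0

  n <- length(x)
  teager <- mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])

  shannon <- shannon_entropy_hist(x)
  ps <- psd / sum(psd)
  spec_ent <- if (sum(psd) <= .Machine$double.eps) 0 else {
    pnz <- ps[ps > 0]
    -sum(pnz * log(pnz))
  }
  sv <- svd_spectrum(x)
  if (is.null(sv)) {
    svd_ent <- 0
    fisher <- 0
  } else {
    pnz <- sv[sv > 0]
    svd_ent <- -sum(pnz * log(pnz))
    dif <- diff(sv)
    ok <- sv[-length(sv)] > 0
    fisher <- sum(dif[ok]^2 / sv[-length(sv)][ok])
  }

  fb_lo <- 0:14
  fb <- vapply(fb_lo, function(lo) band_power(freq, psd, lo, lo + 2), 0)
  # relative floor keeps empty bands (above the effective Nyquist) finite and
  # makes the log-energy vector shift uniformly under amplitude scaling
  tot_fb <- sum(fb)
  log_e <- if (tot_fb > 0) log(fb + 1e-12 * tot_fb) else rep(0, length(fb))
  cep <- dct2(log_e)
  e_pad <- c(0, log_e, 0)
  ff <- e_pad[3:17] - e_pad[1:15]

  pp <- max(x) - min(x)

  out <- c(total_power, peak_freq, sef, bp, nbp, wavelet_d3, wavelet_d4,
           curve_length, extrema, rms, v0, mobility, complexity,
           zcr, zcr1, zcr2, var_d1, var_d2, ar_err, skw, krt, teager,
           shannon, spec_ent, svd_ent, fisher, fb, cep, ff, pp)
  out[!is.finite(out)] <- 0
  names(out) <- feature_manifest()$name
  out
}

#' Extract the epoch x channel x feature tensor for one recording
#'
#' @param recording a preprocessed `eeg_recording` at the working rate.
#' @param grid an `epoch_grid` from [make_epochs()].
#' @param overlap_fraction epoch seizure-labelling rule (see [label_epochs()]).
#' @return a `feature_tensor`: list with `values`
#'   (n_epochs x n_channels x 103 array), `labels`, `epoch_starts_s`,
#'   `epoch_length_s`, `duration_s`, `patient_id`, `cohort`, `channels`,
#'   `feature_names`.
#' @export
extract_tensor <- function(recording, grid, overlap_fraction = 0.5) {
  fs <- recording$sample_rate_hz
  nchn <- nrow(recording$signal)
  man <- feature_manifest()
  vals <- array(0, dim = c(grid$n_epochs, nchn, nrow(man)))
  len <- round(grid$epoch_length_s * fs)
  for (e in seq_len(grid$n_epochs)) {
    i0 <- round(grid$epoch_starts_s[e] * fs) + 1
    idx <- i0:(i0 + len - 1)
    for (ch in seq_len(nchn)) {
      vals[e, ch, ] <- extract_features(recording$signal[ch, idx], fs,
                                        grid$epoch_length_s)
    }
  }
  structure(list(
    values = vals,
    labels = label_epochs(grid, recording$annotations, overlap_fraction),
    epoch_starts_s = grid$epoch_starts_s,
    epoch_length_s = grid$epoch_length_s,
    duration_s = recording$duration_s,
    patient_id = recording$patient_id,
    cohort = recording$cohort,
    channels = recording$channels,
    feature_names = man$name
  ), class = "feature_tensor")
}

#' Flatten a feature tensor to one row per epoch x channel
#'
#' @param tensor a `feature_tensor`.
#' @return list with `X` (numeric matrix, 103 named columns) and `meta`
#'   (data.frame: `patient_id`, `cohort`, `channel`, `epoch`, `epoch_start_s`,
#'   `label`).
#' @export
flatten_tensor <- function(tensor) {
  d <- dim(tensor$values)
  n_e <- d[1]; n_c <- d[2]; n_f <- d[3]
  X <- matrix(aperm(tensor$values, c(1, 2, 3)), nrow = n_e * n_c, ncol = n_f)
  colnames(X) <- tensor$feature_names
  meta <- data.frame(
    patient_id = tensor$patient_id,
    cohort = tensor$cohort,
    channel = rep(tensor$channels, each = n_e),
    epoch = rep(seq_len(n_e), times = n_c),
    epoch_start_s = rep(tensor$epoch_starts_s, times = n_c),
    label = rep(tensor$labels, times = n_c),
    stringsAsFactors = FALSE
  )
  list(X = X, meta = meta)
}

#' Write / read a feature tensor as a flat CSV table
#'
#' One row per epoch x channel: metadata columns followed by the 103 named
#' feature columns.
#'
#' @param tensor a `feature_tensor`.
#' @param path CSV path.
#' @return `path` invisibly (`write_feature_table`); a data.frame
#'   (`read_feature_table`).
#' @export
write_feature_table <- function(tensor, path) {
  fl <- flatten_tensor(tensor)
  df <- cbind(fl$meta,
              epoch_length_s = tensor$epoch_length_s,
              duration_s = tensor$duration_s,
              as.data.frame(fl$X))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
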