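# Shared fixtures (built once per test run) and independent brute-force
# oracles used across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small neonatal-like cohort + tensors, reused by fbc/model/pipeline tests
tiny_cohort_config <- function(seed = 11L, n_patients = 3) {
  cohort_config("neo", n_patients = n_patients, n_channels = 4,
                sample_rate_hz = 100, duration_s = 300,
                seizure_duration_s = c(20, 40), seizure_freq_hz = c(1, 3.5),
                seizure_harmonic = TRUE, seed = seed)
}

tiny_tensors <- function() {
  memo("tiny_tensors", function() {
    cohort_tensors(generate_cohort(tiny_cohort_config()))
  })
}

# a minimal one-feature tensor with controlled aNS (baseline level) and a
# controlled optimal threshold: two identical baseline epochs at `a`, two
# seizure epochs at `a + delta` => aNS = a, Tr = a + delta/2 (midpoint rule)
make_point_tensor <- function(a, tr, patient_id) {
  delta <- 2 * (tr - a)
  vals <- array(c(a, a, a + delta, a + delta), dim = c(4, 1, 1))
  structure(list(
    values = vals,
    labels = c(0L, 0L, 1L, 1L),
    epoch_starts_s = c(0, 5, 10, 15),
    epoch_length_s = 10,
    duration_s = 25,
    patient_id = patient_id,
    cohort = "synthetic",
    channels = "Ch01",
    feature_names = "f1"
  ), class = "feature_tensor")
}

# --- independent oracles ------------------------------------------------------

# pairwise-comparison AUC (Mann-Whitney, ties half-weighted)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden scan over all midpoints between sorted unique values
oracle_threshold <- function(values, labels) {
  u <- sort(unique(values))
  if (length(u) == 1) return(u)
  mids <- (u[-length(u)] + u[-1]) / 2
  J <- vapply(mids, function(t) {
    sens <- mean(values[labels == 1] >= t)
    spec <- mean(values[labels == 0] < t)
    sens + spec - 1
  }, 0)
  best <- max(J)
  hits <- which(J >= best - 1e-12)
  run_end <- hits[1]
  for (h in hits[-1]) { if (h == run_end + 1) run_end <- h else break }
  (u[hits[1]] + u[run_end + 1]) / 2
}

# brute-force false-detection count: enumerate positive segments, check each
# epoch against each annotation interval
oracle_fd_count <- function(decisions, starts, len, ann) {
  fd <- 0L
  in_seg <- FALSE
  seg_overlaps <- FALSE
  for (i in seq_along(decisions)) {
    if (decisions[i] == 1) {
      if (!in_seg) { in_seg <- TRUE; seg_overlaps <- FALSE }
      for (j in seq_len(nrow(ann))) {
        if (starts[i] < ann$end_s[j] && starts[i] + len > ann$start_s[j]) {
          seg_overlaps <- TRUE
        }
      }
    } else if (in_seg) {
      if (!seg_overlaps) fd <- fd + 1L
      in_seg <- FALSE
    }
  }
  if (in_seg && !seg_overlaps) fd <- fd + 1L
  fd
}

# brute-force one-sided DFT periodogram of one Hamming-windowed, mean-removed
# segment (no fft), matching the welch_psd segment definition
oracle_segment_psd <- function(seg, fs) {
  m <- length(seg)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(m - 1)) / (m - 1))
  x <- (seg - mean(seg)) * w
  U <- sum(w^2)
  nfreq <- floor(m / 2) + 1
  psd <- numeric(nfreq)
  for (k in seq_len(nfreq)) {
    re <- sum(x * cos(-2 * pi * (k - 1) * (0:(m - 1)) / m))
    im <- sum(x * sin(-2 * pi * (k - 1) * (0:(m - 1)) / m))
    psd[k] <- (re^2 + im^2) / (fs * U)
    dbl <- if (k == 1 || (m %% 2 == 0 && k == nfreq)) 1 else 2
    psd[k] <- psd[k] * dbl
  }
  psd
}
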