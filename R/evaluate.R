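#' Balance epochs across patients by replication
#'
#' Let Nmax-S and Nmax-NS be the largest per-patient seizure and non-seizure
#' epoch counts. Every patient is brought to exactly those counts by taking
#' multiple copies of its epochs: each epoch is repeated `floor(target/n)`
#' times and the remainder is drawn without replacement (seeded). Patients
#' with only one class contribute only that class. A dataset already balanced
#' is returned unchanged.
#'
#' @param df data.frame with at least `patient_id`, `score`, `label`.
#' @param seed resampling seed.
#' @return the balanced data.frame (rows replicated as needed).
#' @export
balance_patients <- function(df, seed = 1L) {
  if (nrow(df) == 0) stop("empty input")
  counts <- table(df$patient_id, df$label)
  nmax <- apply(counts, 2, max)
  with_seed(seed, {
    keep <- integer(0)
    for (p in rownames(counts)) {
      for (lab in colnames(counts)) {
        rows <- which(df$patient_id == p & df$label == as.integer(lab))
        n <- length(rows)
        if (n == 0) next
        target <- nmax[[lab]]
        times <- target %/% n
        rem <- target - times * n
        sel <- c(rep(rows, times),
                 if (rem > 0) rows[sample.int(n, rem)] else integer(0))
        keep <- c(keep, sel)
      }
    }
    df[keep, , drop = FALSE]
  })
}

#' ROC curve and AUC (trapezoidal)
#'
#' Sensitivity vs specificity over all distinct thresholds of the rule
#' `score >= threshold`. The trapezoidal AUC equals the Mann-Whitney U
#' normalization (ties half-weighted).
#'
#' @param scores numeric scores (higher = more seizure-like).
#' @param labels 0/1 vector; both classes required.
#' @return a `roc_curve`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("both classes required for ROC analysis")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group ties
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(l == 1)[grp_end]
  fp <- cumsum(l == 0)[grp_end]
  sens <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(
    thresholds = c(Inf, s[grp_end]),
    sensitivity = sens,
    specificity = 1 - fpr,
    auc = auc
  ), class = "roc_curve")
}

#' Vertically average ROC curves on a fixed specificity grid
#'
#' Sensitivities are linearly interpolated onto the specificity grid per curve
#' and averaged pointwise (the standard way to combine the Monte Carlo runs'
#' curves).
#'
#' @param curves list of `roc_curve`s.
#' @param specificity_grid grid in [0, 1] (default step 0.01).
#' @return a `roc_curve` on the grid (thresholds are NA), with trapezoidal
#'   `auc` over the grid.
#' @export
vertical_average <- function(curves, specificity_grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(curves) >= 1)
  sens_mat <- vapply(curves, function(cv) {
    o <- order(cv$specificity)
    stats::approx(cv$specificity[o], cv$sensitivity[o],
                  xout = specificity_grid, ties = max, rule = 2)$y
  }, numeric(length(specificity_grid)))
  sens_mat <- matrix(sens_mat, nrow = length(specificity_grid))
  sens <- rowMeans(sens_mat)
  o <- order(specificity_grid)
  fpr <- 1 - specificity_grid[o]
  se <- sens[o]
  oo <- order(fpr)
  auc <- sum(diff(fpr[oo]) * (se[oo][-1] + se[oo][-length(se)]) / 2)
  structure(list(
    thresholds = rep(NA_real_, length(specificity_grid)),
    sensitivity = sens,
    specificity = specificity_grid,
    auc = auc
  ), class = "roc_curve")
}

#' Relative performance gain as percent of the maximal achievable gain
#'
#' `100 * (auc_fbc - auc_no_fbc) / (1 - auc_no_fbc)`; e.g. an AUC improving
#' from 0.8 to 0.9 is a 50% relative gain.
#'
#' @param auc_no_fbc AUC without FBC (< 1).
#' @param auc_fbc AUC with FBC.
#' @return percentage (numeric scalar).
#' @export
relative_gain <- function(auc_no_fbc, auc_fbc) {
  if (auc_no_fbc >= 1) stop("relative gain undefined for auc_no_fbc >= 1")
  100 * (auc_fbc - auc_no_fbc) / (1 - auc_no_fbc)
}

#' Event-based detection metrics: false detections per hour and SDR
#'
#' A false detection is a maximal run of consecutive seizure-positive epochs
#' whose union has zero overlap with every annotated seizure. A seizure counts
#' as detected when at least one epoch overlapping it is positive. Epochs are
#' half-open `[start, start + length)` in seconds.
#'
#' @param decisions 0/1 vector aligned with `epoch_starts_s`.
#' @param epoch_starts_s epoch start times (s).
#' @param epoch_length_s epoch length (s).
#' @param annotations data.frame with `start_s`, `end_s`.
#' @param record_duration_h total recording time in hours.
#' @return an `event_metrics`: list with `fd_count`, `fd_per_hour`,
#'   `n_detected`, `n_seizures`, `sdr`.
#' @export
event_metrics <- function(decisions, epoch_starts_s, epoch_length_s,
                          annotations, record_duration_h) {
  stopifnot(length(decisions) == length(epoch_starts_s),
            record_duration_h > 0)
  merged <- merge_intervals(annotations)
  pos <- which(decisions == 1)
  fd <- 0L
  if (length(pos) > 0) {
    runs <- split(pos, cumsum(c(1, diff(pos) != 1)))
    for (rn in runs) {
      a0 <- epoch_starts_s[rn[1]]
      a1 <- epoch_starts_s[rn[length(rn)]] + epoch_length_s
      if (interval_overlap(a0, a1, merged) == 0) fd <- fd + 1L
    }
  }
  detected <- 0L
  if (nrow(merged) > 0) {
    for (i in seq_len(nrow(merged))) {
      hit <- any(vapply(pos, function(e) {
        interval_overlap(epoch_starts_s[e], epoch_starts_s[e] + epoch_length_s,
                         merged[i, , drop = FALSE]) > 0
      }, logical(1)))
      detected <- detected + as.integer(hit)
    }
  }
  structure(list(
    fd_count = fd,
    fd_per_hour = fd / record_duration_h,
    n_detected = detected,
    n_seizures = nrow(merged),
    sdr = if (nrow(merged) > 0) detected / nrow(merged) else NA_real_
  ), class = "event_metrics")
}

#' Operating threshold achieving a target epoch sensitivity
#'
#' Returns the largest threshold whose sensitivity (for `score >= threshold`)
#' is at least `target`; if the target is unreachable, the smallest score.
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector; both classes required.
#' @param target target sensitivity (default 0.80).
#' @return the threshold.
#' @export
threshold_at_sensitivity <- function(scores, labels, target = 0.80) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("both classes required")
  }
  pos <- sort(scores[labels == 1], decreasing = TRUE)
  k <- ceiling(target * length(pos))
  if (k > length(pos)) return(min(scores))
  pos[k]
}

#' Compare two metric samples (Shapiro-Wilk gate, then t or Wilcoxon)
#'
#' Both groups are tested for normality (Shapiro-Wilk at alpha = 0.05). If
#' both pass, a two-sample t test compares them; otherwise a Wilcoxon rank-sum
#' test. Differences with p < 0.05 are called significant.
#'
#' @param a,b numeric vectors (>= 3 values each).
#' @param alpha normality-gate level.
#' @return list with `test` ("t" or "wilcoxon"), `p_value`, `significant`,
#'   `shapiro_p` (length 2).
#' @export
compare_runs <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) stop("need >= 3 samples per group")
  sw <- c(a = shapiro_p(a), b = shapiro_p(b))
  if (all(sw > alpha)) {
    p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    test <- "wilcoxon"
  }
  list(test = test, p_value = p, significant = p < 0.05, shapiro_p = sw)
}

# Shapiro-Wilk p-value with a defined degenerate fallback (identical values
# are treated as maximally non-normal)
shapiro_p <- function(x) {
  if (stats::sd(x) <= .Machine$double.eps) return(0)
  stats::shapiro.test(x)$p.value
}
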