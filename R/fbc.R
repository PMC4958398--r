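#' Optimal single-feature detection threshold (Youden's J)
#'
#' Scans all candidate thresholds (midpoints between consecutive sorted unique
#' values) for the threshold classifier `value >= Tr` and returns the one
#' maximizing Youden's J = sensitivity + specificity - 1. The J statistic is
#' piecewise constant in the threshold; the returned Tr is the midpoint of the
#' optimal threshold interval (the first such interval if several achieve the
#' maximum). Values are assumed oriented so that seizures take HIGHER values.
#'
#' @param values numeric feature series.
#' @param labels 0/1 series (1 = seizure), same length.
#' @return the threshold, with attribute `"J"` (the achieved Youden index).
#' @export
optimal_threshold <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("optimal_threshold needs both classes present")
  }
  u <- sort(unique(values))
  if (length(u) == 1) {
    out <- u
    attr(out, "J") <- 0
    return(out)
  }
  # J at threshold t in (u[i], u[i+1]]: predictions flip as t passes each value
  ord <- order(values)
  lab_sorted <- labels[ord]
  val_sorted <- values[ord]
  # for each unique value u[i]: number of pos/neg <= u[i]
  grp <- match(val_sorted, u)
  pos_le <- cumsum(lab_sorted == 1)[cumsum(tabulate(grp, length(u)))]
  neg_le <- cumsum(lab_sorted == 0)[cumsum(tabulate(grp, length(u)))]
  # threshold between u[i] and u[i+1]: sens = pos above u[i], spec = neg <= u[i]
  k <- length(u) - 1
  sens <- (n_pos - pos_le[seq_len(k)]) / n_pos
  spec <- neg_le[seq_len(k)] / n_neg
  J <- sens + spec - 1
  best <- max(J)
  hits <- which(J >= best - 1e-12)
  # first contiguous run of maximizers -> optimal interval (u[i], u[j+1])
  run_end <- hits[1]
  for (h in hits[-1]) {
    if (h == run_end + 1) run_end <- h else break
  }
  tr <- (u[hits[1]] + u[run_end + 1]) / 2
  attr(tr, "J") <- best
  tr
}

#' Per-patient baseline profile (aNS values)
#'
#' Averages each feature over the first `n_epochs` non-seizure epochs that lie
#' fully inside the baseline window (default: the first 180 s of the
#' registration), per channel. This automates the visual selection of
#' seizure-free baseline epochs that a clinical reader would perform.
#'
#' @param tensor a `feature_tensor`.
#' @param window_s baseline window length in seconds.
#' @param n_epochs maximum number of baseline epochs to average (all available
#'   are used, and the count recorded, if fewer exist).
#' @return a `baseline_profile`: list with `aNS` (channels x features matrix),
#'   `n_epochs_used`, `patient_id`.
#' @export
compute_baseline <- function(tensor, window_s = 180, n_epochs = 10) {
  inside <- tensor$epoch_starts_s + tensor$epoch_length_s <= window_s + 1e-9
  eligible <- which(inside & tensor$labels == 0)
  if (length(eligible) == 0) {
    stop("no non-seizure epochs available in the first ", window_s, " s")
  }
  sel <- eligible[seq_len(min(n_epochs, length(eligible)))]
  vals <- tensor$values[sel, , , drop = FALSE]
  aNS <- apply(vals, c(2, 3), mean)
  structure(list(aNS = aNS, n_epochs_used = length(sel),
                 patient_id = tensor$patient_id),
            class = "baseline_profile")
}

#' Per-feature orientation signs
#'
#' Global sign s in {+1, -1} per feature so that `s * feature` is on average
#' higher in seizure epochs, fitted by pooling all training tensors.
#'
#' @param tensors list of `feature_tensor` (training patients only).
#' @return numeric vector of +-1, one per feature.
#' @export
fit_orientation <- function(tensors) {
  n_f <- dim(tensors[[1]]$values)[3]
  sum_s <- numeric(n_f); n_s <- 0
  sum_n <- numeric(n_f); n_n <- 0
  for (tn in tensors) {
    is_s <- tn$labels == 1
    n_c <- dim(tn$values)[2]
    if (any(is_s)) {
      sum_s <- sum_s + apply(tn$values[is_s, , , drop = FALSE], 3, sum)
      n_s <- n_s + sum(is_s) * n_c
    }
    if (any(!is_s)) {
      sum_n <- sum_n + apply(tn$values[!is_s, , , drop = FALSE], 3, sum)
      n_n <- n_n + sum(!is_s) * n_c
    }
  }
  if (n_s == 0 || n_n == 0) return(rep(1, n_f))
  ifelse(sum_s / n_s >= sum_n / n_n, 1, -1)
}

#' Precompute annotation-derived thresholds per (patient, channel, feature)
#'
#' For every channel that contains seizure epochs, computes the optimal
#' threshold for each feature under both orientations. Computing the table
#' once lets leave-one-patient-out folds and Monte Carlo runs reuse it (the
#' thresholds depend only on the feature tensors, not on the training draw).
#'
#' @param tensors list of `feature_tensor`.
#' @return data.frame with `patient_id`, `channel`, and matrices bound as
#'   columns `tr_pos_<f>` is avoided: returns a list with `meta` (patient_id,
#'   channel index) and matrices `tr_pos`, `tr_neg` (rows = patient-channel,
#'   cols = features).
#' @export
fbc_threshold_table <- function(tensors) {
  rows <- list()
  tr_pos <- list()
  tr_neg <- list()
  for (tn in tensors) {
    labs <- tn$labels
    if (sum(labs == 1) == 0 || sum(labs == 0) == 0) next
    n_c <- dim(tn$values)[2]
    n_f <- dim(tn$values)[3]
    for (ch in seq_len(n_c)) {
      tp <- numeric(n_f); tm <- numeric(n_f)
      for (f in seq_len(n_f)) {
        v <- tn$values[, ch, f]
        tp[f] <- as.numeric(optimal_threshold(v, labs))
        tm[f] <- as.numeric(optimal_threshold(-v, labs))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = tn$patient_id, channel = ch, stringsAsFactors = FALSE)
      tr_pos[[length(tr_pos) + 1L]] <- tp
      tr_neg[[length(tr_neg) + 1L]] <- tm
    }
  }
  if (length(rows) == 0) stop("no patient-channel with both classes present")
  list(meta = do.call(rbind, rows),
       tr_pos = do.call(rbind, tr_pos),
       tr_neg = do.call(rbind, tr_neg))
}

#' Fit the feature baseline correction model (Tr ~ aNS regression)
#'
#' For each feature, ordinary least squares of the annotation-derived optimal
#' threshold Tr on the average non-seizure baseline value aNS, pooled over all
#' training (patient, channel) points where a Tr is computable (channels
#' containing seizure epochs). Features with fewer than 2 points (or without
#' aNS spread) fall back as documented.
#'
#' @param tensors list of training `feature_tensor`s.
#' @param baselines named list of `baseline_profile`s (names = patient_id).
#' @param signs orientation signs from [fit_orientation()]; computed from
#'   `tensors` if NULL.
#' @param tr_table optional precomputed [fbc_threshold_table()]; rows for
#'   patients not present in `tensors` are ignored.
#' @return an `fbc_model`: data.frame with `feature`, `sign`, `slope`,
#'   `intercept`, `r2`, `n_points`, plus attribute `fallback` (logical vector).
#' @export
fit_fbc <- function(tensors, baselines, signs = NULL, tr_table = NULL) {
  if (is.null(signs)) signs <- fit_orientation(tensors)
  if (is.null(tr_table)) tr_table <- fbc_threshold_table(tensors)
  patients <- vapply(tensors, function(t) t$patient_id, "")
  keep <- tr_table$meta$patient_id %in% patients
  if (!any(keep)) stop("need >= 1 training patient-channel with both classes")
  meta <- tr_table$meta[keep, , drop = FALSE]
  tr_p <- tr_table$tr_pos[keep, , drop = FALSE]
  tr_m <- tr_table$tr_neg[keep, , drop = FALSE]
  n_f <- ncol(tr_p)
  feature_names <- tensors[[1]]$feature_names

  # oriented aNS per table row
  ans <- matrix(0, nrow = nrow(meta), ncol = n_f)
  for (i in seq_len(nrow(meta))) {
    b <- baselines[[meta$patient_id[i]]]
    if (is.null(b)) stop("missing baseline for patient ", meta$patient_id[i])
    ans[i, ] <- b$aNS[meta$channel[i], ]
  }

  slope <- rep(1, n_f); intercept <- rep(0, n_f)
  r2 <- rep(NA_real_, n_f); npts <- integer(n_f)
  fallback <- rep(FALSE, n_f)
  for (f in seq_len(n_f)) {
    s <- signs[f]
    tr <- if (s >= 0) tr_p[, f] else tr_m[, f]
    a <- s * ans[, f]
    ok <- is.finite(tr) & is.finite(a)
    tr <- tr[ok]; a <- a[ok]
    npts[f] <- length(tr)
    if (length(tr) < 2) {
      fallback[f] <- TRUE
      next
    }
    if (stats::sd(a) <= .Machine$double.eps * max(1, abs(mean(a)))) {
      slope[f] <- 0
      intercept[f] <- mean(tr)
      r2[f] <- 0
      next
    }
    fit <- stats::lm.fit(cbind(1, a), tr)
    intercept[f] <- fit$coefficients[1]
    slope[f] <- fit$coefficients[2]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((tr - mean(tr))^2)
    r2[f] <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  }
  out <- data.frame(feature = feature_names, sign = signs, slope = slope,
                    intercept = intercept, r2 = r2, n_points = npts,
                    stringsAsFactors = FALSE)
  attr(out, "fallback") <- fallback
  class(out) <- c("fbc_model", "data.frame")
  out
}

#' Apply feature baseline correction to a tensor
#'
#' Corrected value = `sign * feature - Tr_used`. In `"test"` mode `Tr_used` is
#' always the regression estimate `slope * (sign * aNS) + intercept`; in
#' `"train"` mode the annotation-derived threshold is used on channels where
#' it is computable (channels with seizure epochs), the estimate elsewhere.
#'
#' @param tensor a `feature_tensor`.
#' @param baseline the patient's `baseline_profile`.
#' @param model an `fbc_model`.
#' @param mode `"test"` or `"train"`.
#' @param tr_table precomputed [fbc_threshold_table()] (required data for
#'   `"train"` mode; computed on the fly from `tensor` if NULL).
#' @return the corrected `feature_tensor` (same shape).
#' @export
apply_fbc <- function(tensor, baseline, model, mode = c("test", "train"),
                      tr_table = NULL) {
  mode <- match.arg(mode)
  if (is.null(baseline)) stop("missing baseline profile")
  d <- dim(tensor$values)
  n_c <- d[2]; n_f <- d[3]
  signs <- model$sign
  # estimated thresholds per channel x feature
  aNS_or <- sweep(baseline$aNS, 2, signs, `*`)
  tr_est <- sweep(sweep(aNS_or, 2, model$slope, `*`), 2, model$intercept, `+`)
  tr_used <- tr_est
  if (mode == "train") {
    if (is.null(tr_table)) {
      tr_table <- tryCatch(fbc_threshold_table(list(tensor)),
                           error = function(e) NULL)
    }
    if (!is.null(tr_table)) {
      sel <- which(tr_table$meta$patient_id == tensor$patient_id)
      for (i in sel) {
        ch <- tr_table$meta$channel[i]
        tr_ann <- ifelse(signs >= 0, tr_table$tr_pos[i, ], tr_table$tr_neg[i, ])
        tr_used[ch, ] <- tr_ann
      }
    }
  }
  out <- tensor
  vals <- tensor$values
  for (ch in seq_len(n_c)) {
    m <- vals[, ch, , drop = FALSE]
    dim(m) <- c(d[1], n_f)
    m <- sweep(m, 2, signs, `*`)
    m <- sweep(m, 2, tr_used[ch, ], `-`)
    out$values[, ch, ] <- m
  }
  out
}

#' Serialize / load an FBC model
#'
#' @param model an `fbc_model`.
#' @param path CSV path.
#' @return `path` invisibly; `read_fbc_model` returns the model.
#' @export
write_fbc_model <- function(model, path) {
  utils::write.csv(as.data.frame(model), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fbc_model
#' @export
read_fbc_model <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("fbc_model", "data.frame")
  out
}
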