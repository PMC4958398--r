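#' Training-set composition specification
#'
#' Target numbers of seizure / non-seizure feature vectors, the per-patient
#' per-channel cap on seizure draws, and the sampling seed. Per-patient quotas
#' are equal (largest-remainder rounding) so each patient contributes equally.
#'
#' @param target_seizure_fvs total seizure feature vectors to draw.
#' @param target_nonseizure_fvs total non-seizure feature vectors to draw.
#' @param max_seizure_per_patient_channel cap on seizure FVs drawn per patient
#'   per channel (default 24).
#' @param seed sampling seed.
#' @return a `training_set_spec`.
#' @export
training_set_spec <- function(target_seizure_fvs = 4500,
                              target_nonseizure_fvs = 9000,
                              max_seizure_per_patient_channel = 24,
                              seed = 1L) {
  stopifnot(target_seizure_fvs >= 1, target_nonseizure_fvs >= 1,
            max_seizure_per_patient_channel >= 1)
  structure(list(
    target_seizure_fvs = as.integer(target_seizure_fvs),
    target_nonseizure_fvs = as.integer(target_nonseizure_fvs),
    max_seizure_per_patient_channel = as.integer(max_seizure_per_patient_channel),
    seed = as.integer(seed)
  ), class = "training_set_spec")
}

# largest-remainder allocation of `total` over n equal shares
largest_remainder <- function(total, n) {
  base <- total %/% n
  rem <- total - base * n
  base + as.integer(seq_len(n) <= rem)
}

#' Assemble a class-balanced, patient-weighted training set
#'
#' Flattens the tensors to feature vectors and draws, per patient, an equal
#' quota of seizure and of non-seizure FVs (sampling without replacement
#' within a patient), with at most `max_seizure_per_patient_channel` seizure
#' FVs per channel. If a patient cannot fill its quota, all its available FVs
#' are taken and the shortfall is recorded.
#'
#' @param tensors list of `feature_tensor`s (training patients).
#' @param spec a [training_set_spec()].
#' @return list with `X` (matrix), `labels` (0/1), `meta` (provenance
#'   data.frame with `patient_id`, `cohort`, `channel`, `label`) and
#'   `shortfall` (data.frame of unmet quotas, possibly empty).
#' @export
assemble_training_set <- function(tensors, spec) {
  flat <- lapply(tensors, flatten_tensor)
  X <- do.call(rbind, lapply(flat, `[[`, "X"))
  meta <- do.call(rbind, lapply(flat, `[[`, "meta"))
  patients <- unique(meta$patient_id)
  n_p <- length(patients)
  q_s <- largest_remainder(spec$target_seizure_fvs, n_p)
  q_n <- largest_remainder(spec$target_nonseizure_fvs, n_p)
  cap <- spec$max_seizure_per_patient_channel

  with_seed(spec$seed, {
    take <- integer(0)
    shortfall <- list()
    for (i in seq_along(patients)) {
      p <- patients[i]
      rows_p <- which(meta$patient_id == p)
      seiz <- rows_p[meta$label[rows_p] == 1]
      nons <- rows_p[meta$label[rows_p] == 0]
      # per-channel cap on the seizure pool
      pool <- integer(0)
      for (ch in unique(meta$channel[seiz])) {
        rows_ch <- seiz[meta$channel[seiz] == ch]
        if (length(rows_ch) > cap) {
          rows_ch <- rows_ch[sample.int(length(rows_ch), cap)]
        }
        pool <- c(pool, rows_ch)
      }
      sel_s <- if (length(pool) <= q_s[i]) pool else
        pool[sample.int(length(pool), q_s[i])]
      sel_n <- if (length(nons) <= q_n[i]) nons else
        nons[sample.int(length(nons), q_n[i])]
      if (length(sel_s) < q_s[i] || length(sel_n) < q_n[i]) {
        shortfall[[length(shortfall) + 1L]] <- data.frame(
          patient_id = p,
          seizure_missing = q_s[i] - length(sel_s),
          nonseizure_missing = q_n[i] - length(sel_n))
      }
      take <- c(take, sel_s, sel_n)
    }
    take <- sort(take)
    list(
      X = X[take, , drop = FALSE],
      labels = meta$label[take],
      meta = meta[take, c("patient_id", "cohort", "channel", "label")],
      shortfall = if (length(shortfall)) do.call(rbind, shortfall) else
        data.frame(patient_id = character(0), seizure_missing = integer(0),
                   nonseizure_missing = integer(0))
    )
  })
}

#' Fit / apply per-feature standardization
#'
#' Subtract the training mean and divide by the training (population) standard
#' deviation per feature. Test data are always standardized with the training
#' parameters. Zero-variance features get a guard sd of 1.
#'
#' @param X training feature matrix.
#' @return a `standardizer`: list with `mean`, `sd`.
#' @export
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sdv[!is.finite(sdv) | sdv <= .Machine$double.eps] <- 1
  structure(list(mean = mu, sd = sdv), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params a `standardizer` fitted on training data.
#' @export
apply_standardizer <- function(X, params) {
  sweep(sweep(X, 2, params$mean, `-`), 2, params$sd, `/`)
}

#' Train a Gaussian-kernel soft-margin SVM seizure classifier
#'
#' Kernel k(u, v) = exp(-||u - v||^2 / (2 sigma^2)); the classifier output is
#' the signed distance from the decision surface, oriented so that seizure
#' (label 1) scores positive.
#'
#' @param X standardized feature matrix.
#' @param labels 0/1 vector (1 = seizure); both classes required.
#' @param C box constraint.
#' @param sigma Gaussian kernel width.
#' @param provenance optional data.frame (one row per training FV, e.g.
#'   `cohort`, `label`) stored for support-vector composition analysis.
#' @param tolerance libsvm termination tolerance.
#' @return a `seizure_classifier`: list with the fitted svm, `C`, `sigma`,
#'   `provenance`, `sv_index`.
#' @export
train_svm <- function(X, labels, C, sigma, provenance = NULL,
                      tolerance = 0.001) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes required to train an SVM")
  fit <- e1071::svm(x = X, y = factor(labels, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = C, scale = FALSE,
                    tolerance = tolerance)
  # orientation of libsvm decision values: positive must mean seizure (the
  # reported column is "<first>/<second>"; positive favours the first class)
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- identical(colnames(dv)[1], "0/1")
  structure(list(fit = fit, C = C, sigma = sigma, flip = flip,
                 provenance = provenance, sv_index = fit$index,
                 n_features = ncol(X)),
            class = "seizure_classifier")
}

#' Signed distance from the decision surface
#'
#' @param clf a `seizure_classifier`.
#' @param X standardized feature matrix.
#' @return numeric vector of decision values (positive = seizure side).
#' @export
decision_values <- function(clf, X) {
  dv <- attr(stats::predict(clf$fit, X, decision.values = TRUE),
             "decision.values")
  out <- drop(dv[, 1])
  if (clf$flip) out <- -out
  unname(out)
}

#' Grid search for (C, sigma) by patient-grouped inner cross-validation
#'
#' Patients are split into `n_folds` groups; for each grid cell an SVM is
#' trained on the out-of-fold FVs and scored by ROC AUC on the held-out fold;
#' the cell with the highest mean AUC wins. Ties go to smaller C, then smaller
#' sigma. Default grids bracket the useful region (C 10-100, sigma 4-9).
#'
#' @param X standardized feature matrix.
#' @param labels 0/1 vector.
#' @param patient_ids patient id per row (grouping factor).
#' @param C_grid,sigma_grid candidate values.
#' @param n_folds inner folds (capped at the number of patients).
#' @param seed fold-assignment seed.
#' @return list with `C`, `sigma` and `auc_table` (full grid results).
#' @export
grid_search <- function(X, labels, patient_ids,
                        C_grid = c(10, 20, 40, 50, 100),
                        sigma_grid = 4:9, n_folds = 5, seed = 1L) {
  stopifnot(length(C_grid) >= 1, length(sigma_grid) >= 1)
  patients <- unique(patient_ids)
  n_folds <- min(n_folds, length(patients))
  fold_of <- with_seed(seed, {
    f <- rep_len(seq_len(n_folds), length(patients))
    f[sample.int(length(patients))]
  })
  names(fold_of) <- patients
  row_fold <- fold_of[patient_ids]

  cells <- expand.grid(C = C_grid, sigma = sigma_grid)
  cells$auc <- NA_real_
  for (i in seq_len(nrow(cells))) {
    aucs <- c()
    for (k in seq_len(n_folds)) {
      tr <- row_fold != k
      te <- !tr
      if (length(unique(labels[tr])) < 2 || length(unique(labels[te])) < 2) next
      clf <- train_svm(X[tr, , drop = FALSE], labels[tr],
                       C = cells$C[i], sigma = cells$sigma[i])
      sc <- decision_values(clf, X[te, , drop = FALSE])
      aucs <- c(aucs, roc_auc(sc, labels[te])$auc)
    }
    cells$auc[i] <- if (length(aucs)) mean(aucs) else NA_real_
  }
  ok <- which(is.finite(cells$auc))
  best <- ok[order(-cells$auc[ok], cells$C[ok], cells$sigma[ok])][1]
  list(C = cells$C[best], sigma = cells$sigma[best], auc_table = cells)
}

#' Printed per-scenario (C, sigma) presets
#'
#' Named list of the grid-search optima per train-test scenario used as
#' defaults by [run_experiment()]: names are `<test cohort>_<training set>`
#' with training sets `adult` (ACP), `neo` (NCP), `combi` (CCP).
#'
#' @return named list of `c(C, sigma)` pairs.
#' @export
svm_param_presets <- function() {
  list(
    adult_adult = c(C = 40, sigma = 7),
    adult_neo   = c(C = 40, sigma = 5),
    adult_combi = c(C = 50, sigma = 6),
    neo_adult   = c(C = 20, sigma = 8),
    neo_neo     = c(C = 20, sigma = 8),
    neo_combi   = c(C = 50, sigma = 6)
  )
}

#' Support-vector composition of a trained classifier
#'
#' Fractions of support vectors by training-subset provenance: per cohort
#' (summing to 1), per cohort x class, and the fraction of each subset's
#' training FVs that became support vectors.
#'
#' @param clf a `seizure_classifier` trained with `provenance`.
#' @return list with `by_cohort`, `by_cohort_class` data.frames.
#' @export
sv_composition <- function(clf) {
  if (is.null(clf$provenance)) stop("classifier has no provenance information")
  prov <- clf$provenance
  svp <- prov[clf$sv_index, , drop = FALSE]
  n_sv <- nrow(svp)
  by_cohort <- as.data.frame(table(cohort = svp$cohort),
                             responseName = "n_sv")
  by_cohort$sv_fraction <- by_cohort$n_sv / n_sv
  cc <- as.data.frame(table(cohort = svp$cohort, label = svp$label),
                      responseName = "n_sv")
  tot <- as.data.frame(table(cohort = prov$cohort, label = prov$label),
                       responseName = "n_train")
  cc <- merge(cc, tot, by = c("cohort", "label"), all.y = TRUE)
  cc$n_sv[is.na(cc$n_sv)] <- 0
  cc$sv_fraction_of_all_svs <- cc$n_sv / n_sv
  cc$fraction_of_subset_becoming_sv <- ifelse(cc$n_train > 0,
                                              cc$n_sv / cc$n_train, NA)
  list(by_cohort = by_cohort, by_cohort_class = cc)
}
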