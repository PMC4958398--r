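#' Detection pipeline configuration
#'
#' Bundles the tunables of one train/test scenario.
#'
#' @param fbc apply feature baseline correction.
#' @param C,sigma SVM parameters.
#' @param target_seizure_fvs,target_nonseizure_fvs,max_seizure_per_patient_channel
#'   training-set composition (see [training_set_spec()]).
#' @param kalman_q,kalman_r Kalman post-processing parameters.
#' @param filter_ranks which sorted rank series to filter (see
#'   [postprocess_outputs()]).
#' @param baseline_window_s,baseline_epochs FBC baseline selection (see
#'   [compute_baseline()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fbc = TRUE, C = 40, sigma = 7,
                            target_seizure_fvs = 200,
                            target_nonseizure_fvs = 400,
                            max_seizure_per_patient_channel = 24,
                            kalman_q = 0.01, kalman_r = 1,
                            filter_ranks = "all",
                            baseline_window_s = 180, baseline_epochs = 10) {
  structure(list(
    fbc = isTRUE(fbc), C = C, sigma = sigma,
    target_seizure_fvs = target_seizure_fvs,
    target_nonseizure_fvs = target_nonseizure_fvs,
    max_seizure_per_patient_channel = max_seizure_per_patient_channel,
    kalman_q = kalman_q, kalman_r = kalman_r, filter_ranks = filter_ranks,
    baseline_window_s = baseline_window_s, baseline_epochs = baseline_epochs
  ), class = "pipeline_config")
}

baselines_for <- function(tensors, config) {
  out <- lapply(tensors, compute_baseline,
                window_s = config$baseline_window_s,
                n_epochs = config$baseline_epochs)
  names(out) <- vapply(tensors, function(t) t$patient_id, "")
  out
}

#' Train a complete seizure detector on a set of patients' tensors
#'
#' Fits (in order, on training patients only): feature orientation signs, the
#' FBC threshold regression (if enabled), the training-set draw, the feature
#' standardizer and the Gaussian SVM. Nothing from any later test patient
#' enters any of these fits.
#'
#' @param train_tensors list of `feature_tensor`s.
#' @param config a [pipeline_config()].
#' @param seed training-set sampling seed.
#' @param tr_table optional precomputed [fbc_threshold_table()] covering the
#'   training patients (a speed-up only; recomputed if NULL and FBC is on).
#' @return a `seizure_detector`: list with `config`, `signs`, `fbc_model`,
#'   `standardizer`, `classifier`, `shortfall`.
#' @export
train_detector <- function(train_tensors, config, seed = 1L, tr_table = NULL) {
  signs <- fit_orientation(train_tensors)
  fbc_model <- NULL
  work <- train_tensors
  if (config$fbc) {
    if (is.null(tr_table)) tr_table <- fbc_threshold_table(train_tensors)
    bls <- baselines_for(train_tensors, config)
    fbc_model <- fit_fbc(train_tensors, bls, signs = signs,
                         tr_table = tr_table)
    work <- lapply(train_tensors, function(tn) {
      apply_fbc(tn, bls[[tn$patient_id]], fbc_model, mode = "train",
                tr_table = tr_table)
    })
  }
  ts <- assemble_training_set(work, training_set_spec(
    target_seizure_fvs = config$target_seizure_fvs,
    target_nonseizure_fvs = config$target_nonseizure_fvs,
    max_seizure_per_patient_channel = config$max_seizure_per_patient_channel,
    seed = seed))
  st <- fit_standardizer(ts$X)
  Xs <- apply_standardizer(ts$X, st)
  clf <- train_svm(Xs, ts$labels, C = config$C, sigma = config$sigma,
                   provenance = ts$meta)
  structure(list(config = config, signs = signs, fbc_model = fbc_model,
                 standardizer = st, classifier = clf,
                 shortfall = ts$shortfall),
            class = "seizure_detector")
}

#' Score one patient's recording with a trained detector
#'
#' Applies (test-mode) FBC with the patient's own baseline, the training
#' standardizer and the SVM per channel, then sorts / Kalman-filters /
#' max-reduces the outputs into one multi-channel score per epoch.
#'
#' @param detector a `seizure_detector`.
#' @param tensor the test patient's `feature_tensor`.
#' @return data.frame with `patient_id`, `epoch`, `epoch_start_s`, `label`,
#'   `score`; attributes `epoch_length_s`, `duration_s`, `annotations` are
#'   carried for event metrics.
#' @export
score_tensor <- function(detector, tensor) {
  cfg <- detector$config
  work <- tensor
  if (cfg$fbc) {
    bl <- compute_baseline(tensor, window_s = cfg$baseline_window_s,
                           n_epochs = cfg$baseline_epochs)
    work <- apply_fbc(tensor, bl, detector$fbc_model, mode = "test")
  }
  d <- dim(work$values)
  raw <- matrix(0, nrow = d[1], ncol = d[2])
  for (ch in seq_len(d[2])) {
    Xc <- work$values[, ch, , drop = FALSE]
    dim(Xc) <- c(d[1], d[3])
    Xc <- apply_standardizer(Xc, detector$standardizer)
    raw[, ch] <- decision_values(detector$classifier, Xc)
  }
  pp <- postprocess_outputs(raw, q = cfg$kalman_q, r = cfg$kalman_r,
                            filter_ranks = cfg$filter_ranks)
  out <- data.frame(patient_id = tensor$patient_id,
                    epoch = seq_len(d[1]),
                    epoch_start_s = tensor$epoch_starts_s,
                    label = tensor$labels,
                    score = pp$score,
                    stringsAsFactors = FALSE)
  attr(out, "epoch_length_s") <- tensor$epoch_length_s
  attr(out, "duration_s") <- tensor$duration_s
  out
}

#' Leave-one-patient-out cross-validation
#'
#' For every patient, a detector is trained on all other patients' tensors
#' (orientation, FBC, training draw, standardizer, SVM) and the held-out
#' patient is scored. The held-out patient's data influence nothing fitted.
#'
#' @param tensors list of `feature_tensor`s, one entry per patient-recording;
#'   all tensors sharing a `patient_id` are held out together.
#' @param config a [pipeline_config()].
#' @param seed training-draw seed (one derived seed per fold).
#' @param tr_table optional precomputed [fbc_threshold_table()] for all
#'   tensors (reused across folds; per-fold fits still exclude the held-out
#'   patient's rows).
#' @param holdout_patients patients to hold out and score (default: all);
#'   training always uses all patients except the one held out.
#' @return data.frame of per-epoch scores for all patients (rbind of
#'   [score_tensor()] outputs, with `fold` column).
#' @export
loo_crossval <- function(tensors, config, seed = 1L, tr_table = NULL,
                         holdout_patients = NULL) {
  pids <- vapply(tensors, function(t) t$patient_id, "")
  patients <- unique(pids)
  if (length(patients) < 2) stop("leave-one-patient-out needs >= 2 patients")
  if (config$fbc && is.null(tr_table)) {
    tr_table <- fbc_threshold_table(tensors)
  }
  folds <- if (is.null(holdout_patients)) patients else
    patients[patients %in% holdout_patients]
  out <- list()
  for (i in seq_along(folds)) {
    p <- folds[i]
    train <- tensors[pids != p]
    det <- train_detector(train, config, seed = derive_seed(seed, i),
                          tr_table = tr_table)
    for (tn in tensors[pids == p]) {
      sc <- score_tensor(det, tn)
      sc$fold <- i
      out[[length(out) + 1L]] <- sc
    }
  }
  do.call(rbind, out)
}

#' Train on one cohort, test on another (single classifier)
#'
#' Cross-cohort protocol: one detector is trained on all training-cohort
#' patients and applied to every test-cohort patient.
#'
#' @param train_tensors,test_tensors lists of `feature_tensor`s.
#' @param config a [pipeline_config()].
#' @param seed training-draw seed.
#' @param tr_table optional precomputed threshold table for `train_tensors`.
#' @return data.frame of per-epoch scores for the test patients.
#' @export
cross_cohort <- function(train_tensors, test_tensors, config, seed = 1L,
                         tr_table = NULL) {
  det <- train_detector(train_tensors, config, seed = seed,
                        tr_table = tr_table)
  out <- lapply(test_tensors, score_tensor, detector = det)
  do.call(rbind, out)
}

#' Patient-balanced AUC of a score table
#'
#' @param scores data.frame from [loo_crossval()] / [cross_cohort()].
#' @param seed balancing seed.
#' @return the balanced AUC (scalar).
#' @export
balanced_auc <- function(scores, seed = 1L) {
  bal <- balance_patients(scores, seed = seed)
  roc_auc(bal$score, bal$label)$auc
}

#' Monte Carlo repetition of a run function
#'
#' Runs `run_fn(seed_r)` for `n_runs` derived seeds and reports the per-run
#' values with their mean and sd.
#'
#' @param run_fn function of one argument (the run seed) returning a scalar
#'   metric or a list of metrics.
#' @param n_runs number of Monte Carlo runs (>= 2).
#' @param master_seed master seed; run r uses `derive_seed(master_seed, r)`.
#' @return list with `runs` (list of results), `values` (numeric vector if
#'   scalar), `mean`, `sd`.
#' @export
monte_carlo <- function(run_fn, n_runs = 10, master_seed = 1L) {
  stopifnot(n_runs >= 2)
  runs <- lapply(seq_len(n_runs), function(r) run_fn(derive_seed(master_seed, r)))
  if (all(vapply(runs, is.numeric, TRUE)) &&
      all(lengths(runs) == 1L)) {
    v <- unlist(runs)
    list(runs = runs, values = v, mean = mean(v), sd = stats::sd(v))
  } else {
    list(runs = runs, values = NULL, mean = NULL, sd = NULL)
  }
}

#' Build feature tensors for a cohort of recordings
#'
#' Convenience wrapper: band-pass, down-sample, epoch and extract features for
#' every recording.
#'
#' @param recordings list of `eeg_recording`s.
#' @param low_hz,high_hz,target_hz,epoch_length_s,stride_s,anti_alias see
#'   [preprocess_recording()].
#' @param overlap_fraction epoch labelling rule.
#' @return list of `feature_tensor`s.
#' @export
cohort_tensors <- function(recordings, low_hz = 0.5, high_hz = 32,
                           target_hz = 25, epoch_length_s = 10, stride_s = 5,
                           anti_alias = TRUE, overlap_fraction = 0.5) {
  lapply(recordings, function(rec) {
    pp <- preprocess_recording(rec, low_hz, high_hz, target_hz,
                               epoch_length_s, stride_s, anti_alias)
    extract_tensor(pp$recording, pp$grid, overlap_fraction)
  })
}

#' Experiment configuration: the full training-composition matrix
#'
#' Describes the 3 training sets (neo, adult, combi) x 2 test cohorts x
#' {FBC, no FBC} = 12-cell evaluation matrix with Monte Carlo repetition.
#'
#' @param neo_config,adult_config [cohort_config()]s for the two cohorts.
#' @param n_monte_carlo Monte Carlo runs per cell.
#' @param master_seed master seed for all randomness.
#' @param target_seizure_fvs,target_nonseizure_fvs per-training-set draw sizes
#'   (combi uses their sums).
#' @param svm_params named list of `c(C, sigma)` per cell
#'   (default [svm_param_presets()]).
#' @param kalman_q,kalman_r post-processing parameters.
#' @param target_hz,low_hz,high_hz,epoch_length_s,stride_s preprocessing.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(neo_config, adult_config,
                              n_monte_carlo = 10, master_seed = 1L,
                              target_seizure_fvs = 200,
                              target_nonseizure_fvs = 400,
                              svm_params = svm_param_presets(),
                              kalman_q = 0.01, kalman_r = 1,
                              target_hz = 25, low_hz = 0.5, high_hz = 32,
                              epoch_length_s = 10, stride_s = 5) {
  structure(list(
    neo_config = neo_config, adult_config = adult_config,
    n_monte_carlo = n_monte_carlo, master_seed = as.integer(master_seed),
    target_seizure_fvs = target_seizure_fvs,
    target_nonseizure_fvs = target_nonseizure_fvs,
    svm_params = svm_params, kalman_q = kalman_q, kalman_r = kalman_r,
    target_hz = target_hz, low_hz = low_hz, high_hz = high_hz,
    epoch_length_s = epoch_length_s, stride_s = stride_s
  ), class = "experiment_config")
}

#' Run the full 12-cell training-composition experiment
#'
#' Generates (or accepts) the two cohorts, extracts features once, then for
#' every cell (training set x test cohort x FBC on/off) repeats the complete
#' training-and-testing procedure `n_monte_carlo` times with fresh training
#' draws. Cells whose training set contains the test cohort use
#' leave-one-patient-out; pure cross-cohort cells train a single classifier.
#' Patient-balanced AUCs are reported per run with mean, sd and the relative
#' gain of FBC over no FBC.
#'
#' @param config an [experiment_config()].
#' @param tensors optional precomputed list with elements `neo`, `adult`
#'   (lists of `feature_tensor`s); generated from the cohort configs if NULL.
#' @return an `evaluation_report`: list with `summary` (one row per cell:
#'   mean/sd AUC, C, sigma), `gains` (relative gain per train x test cell),
#'   `runs` (per-run AUC long data.frame), `config`.
#' @export
run_experiment <- function(config, tensors = NULL) {
  if (is.null(tensors)) {
    tensors <- list(
      neo = cohort_tensors(generate_cohort(config$neo_config),
                           config$low_hz, config$high_hz, config$target_hz,
                           config$epoch_length_s, config$stride_s),
      adult = cohort_tensors(generate_cohort(config$adult_config),
                             config$low_hz, config$high_hz, config$target_hz,
                             config$epoch_length_s, config$stride_s)
    )
  }
  tr_tables <- list(neo = fbc_threshold_table(tensors$neo),
                    adult = fbc_threshold_table(tensors$adult))
  tr_tables$combi <- list(
    meta = rbind(tr_tables$neo$meta, tr_tables$adult$meta),
    tr_pos = rbind(tr_tables$neo$tr_pos, tr_tables$adult$tr_pos),
    tr_neg = rbind(tr_tables$neo$tr_neg, tr_tables$adult$tr_neg))

  train_sets <- list(neo = tensors$neo, adult = tensors$adult,
                     combi = c(tensors$neo, tensors$adult))
  runs <- list()
  cell_id <- 0L
  for (test_cohort in c("neo", "adult")) {
    for (train_name in c("neo", "adult", "combi")) {
      params <- config$svm_params[[paste0(test_cohort, "_", train_name)]]
      if (is.null(params)) params <- c(C = 40, sigma = 6)
      mult <- if (train_name == "combi") 2 else 1
      for (fbc in c(FALSE, TRUE)) {
        cell_id <- cell_id + 1L
        pc <- pipeline_config(
          fbc = fbc, C = params[["C"]], sigma = params[["sigma"]],
          target_seizure_fvs = config$target_seizure_fvs * mult,
          target_nonseizure_fvs = config$target_nonseizure_fvs * mult,
          kalman_q = config$kalman_q, kalman_r = config$kalman_r)
        cell_seed <- derive_seed(config$master_seed, cell_id)
        includes_test <- train_name == test_cohort || train_name == "combi"
        for (r in seq_len(config$n_monte_carlo)) {
          run_seed <- derive_seed(cell_seed, r)
          if (includes_test) {
            test_ids <- vapply(tensors[[test_cohort]],
                               function(t) t$patient_id, "")
            sc <- loo_crossval(train_sets[[train_name]], pc, seed = run_seed,
                               tr_table = if (fbc) tr_tables[[train_name]],
                               holdout_patients = test_ids)
          } else {
            sc <- cross_cohort(train_sets[[train_name]],
                               tensors[[test_cohort]], pc, seed = run_seed,
                               tr_table = if (fbc) tr_tables[[train_name]])
          }
          auc <- balanced_auc(sc, seed = derive_seed(run_seed, 99))
          runs[[length(runs) + 1L]] <- data.frame(
            test_cohort = test_cohort, train_set = train_name,
            fbc = fbc, run = r, auc = auc,
            C = params[["C"]], sigma = params[["sigma"]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  agg <- stats::aggregate(auc ~ test_cohort + train_set + fbc, data = runs,
                          FUN = mean)
  names(agg)[names(agg) == "auc"] <- "auc_mean"
  agg_sd <- stats::aggregate(auc ~ test_cohort + train_set + fbc, data = runs,
                             FUN = stats::sd)
  names(agg_sd)[names(agg_sd) == "auc"] <- "auc_sd"
  agg <- merge(agg, agg_sd, by = c("test_cohort", "train_set", "fbc"))
  agg <- merge(agg, unique(runs[, c("test_cohort", "train_set", "C", "sigma")]),
               by = c("test_cohort", "train_set"))
  gains <- NULL
  for (tc in c("neo", "adult")) {
    for (tr in c("neo", "adult", "combi")) {
      a0 <- agg$auc_mean[agg$test_cohort == tc & agg$train_set == tr & !agg$fbc]
      a1 <- agg$auc_mean[agg$test_cohort == tc & agg$train_set == tr & agg$fbc]
      g <- if (a0 < 1) relative_gain(a0, a1) else NA_real_
      gains <- rbind(gains, data.frame(test_cohort = tc, train_set = tr,
                                       auc_no_fbc = a0, auc_fbc = a1,
                                       relative_gain_pct = g))
    }
  }
  structure(list(summary = agg, gains = gains, runs = runs, config = config),
            class = "evaluation_report")
}

#' Write an evaluation report to disk (JSON + CSV)
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  utils::write.csv(report$gains, file.path(dir, "gains.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, gains = report$gains),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
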