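test_that("optimal threshold: midpoint rule, order invariance, oracle equality", {
  expect_equal(as.numeric(optimal_threshold(c(1, 2, 8, 9), c(0, 0, 1, 1))), 5)
  expect_equal(as.numeric(optimal_threshold(c(1, 9, 2, 8), c(0, 1, 0, 1))), 5)
  v <- c(1, 2, 3, 8, 2.5, 9); l <- c(0, 0, 0, 1, 1, 1)
  expect_equal(as.numeric(optimal_threshold(v, l)), oracle_threshold(v, l))
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    vals <- round(rnorm(n), sample(0:2, 1))   # ties included
    labs <- rbinom(n, 1, 0.4)
    if (sum(labs) == 0 || sum(labs) == n) next
    expect_equal(as.numeric(optimal_threshold(vals, labs)),
                 oracle_threshold(vals, labs))
  }
  expect_error(optimal_threshold(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("baseline profile averages the first non-seizure epochs of the window", {
  tn <- tiny_tensors()[[1]]
  bl <- compute_baseline(tn, window_s = 180, n_epochs = 10)
  eligible <- which(tn$epoch_starts_s + tn$epoch_length_s <= 180 + 1e-9 &
                      tn$labels == 0)[1:10]
  expect_equal(bl$aNS[2, 5], mean(tn$values[eligible, 2, 5]))
  expect_equal(bl$n_epochs_used, 10)
  # n_epochs larger than available -> all available, count recorded
  bl2 <- compute_baseline(tn, window_s = 60, n_epochs = 999)
  expect_lt(bl2$n_epochs_used, 999)
  expect_gt(bl2$n_epochs_used, 0)
  # seizure epochs are excluded by construction of `eligible`
  tn_bad <- tn
  tn_bad$labels[] <- 1L
  expect_error(compute_baseline(tn_bad), "no non-seizure")
})

test_that("fit_fbc recovers an exact linear Tr~aNS relation to machine precision", {
  a <- seq(0.5, 3, length.out = 12)
  tensors <- lapply(seq_along(a), function(i) {
    make_point_tensor(a[i], tr = 2 * a[i] + 1, patient_id = sprintf("p%02d", i))
  })
  baselines <- lapply(tensors, compute_baseline)
  names(baselines) <- vapply(tensors, function(t) t$patient_id, "")
  model <- fit_fbc(tensors, baselines)
  expect_equal(model$slope, 2, tolerance = 1e-10)
  expect_equal(model$intercept, 1, tolerance = 1e-10)
  expect_equal(model$sign, 1)
  expect_gt(model$r2, 1 - 1e-10)
})

test_that("degenerate regressions fall back as documented", {
  # constant aNS across points -> slope 0, intercept mean(Tr)
  trs <- c(1.5, 2.5, 3.5)
  tensors <- lapply(seq_along(trs), function(i) {
    make_point_tensor(1, tr = trs[i], patient_id = sprintf("q%d", i))
  })
  baselines <- lapply(tensors, compute_baseline)
  names(baselines) <- vapply(tensors, function(t) t$patient_id, "")
  model <- fit_fbc(tensors, baselines)
  expect_equal(model$slope, 0)
  expect_equal(model$intercept, mean(trs))
  # single point -> fallback slope 1 intercept 0
  t1 <- list(make_point_tensor(1, 2, "solo"))
  b1 <- list(solo = compute_baseline(t1[[1]]))
  m1 <- suppressWarnings(fit_fbc(t1, b1))
  expect_equal(m1$slope, 1)
  expect_equal(m1$intercept, 0)
  expect_true(attr(m1, "fallback")[1])
})

test_that("apply_fbc subtracts the estimated threshold; slope 1 intercept 0 is aNS subtraction", {
  tn <- make_point_tensor(2, tr = 5, patient_id = "z")
  bl <- compute_baseline(tn)
  model <- data.frame(feature = "f1", sign = 1, slope = 1, intercept = 0,
                      r2 = NA, n_points = 0)
  class(model) <- c("fbc_model", "data.frame")
  out <- apply_fbc(tn, bl, model, mode = "test")
  expect_equal(out$values[, 1, 1], tn$values[, 1, 1] - 2)   # aNS = 2
  # estimated Tr = slope*aNS + intercept: feature 5, Tr 3 -> corrected 2
  model2 <- model; model2$slope <- 0; model2$intercept <- 3
  out2 <- apply_fbc(tn, bl, model2, mode = "test")
  expect_equal(out2$values[3, 1, 1], tn$values[3, 1, 1] - 3)
  # train mode uses the annotation-derived threshold (Tr = 5 here)
  out3 <- apply_fbc(tn, bl, model2, mode = "train")
  expect_equal(out3$values[, 1, 1], tn$values[, 1, 1] - 5)
})

test_that("after FBC the per-patient optimal thresholds collapse towards zero", {
  tns <- tiny_tensors()
  tt <- fbc_threshold_table(tns)
  signs <- fit_orientation(tns)
  baselines <- lapply(tns, compute_baseline)
  names(baselines) <- vapply(tns, function(t) t$patient_id, "")
  model <- fit_fbc(tns, baselines, signs = signs, tr_table = tt)
  # correct in test mode (estimated thresholds only), then re-measure Tr
  man <- feature_manifest()
  check_idx <- which(man$name %in% c("rms", "total_power_0_12", "curve_length",
                                     "bp_1_3", "hjorth_activity"))
  for (f_idx in check_idx) {
    trs <- c(); sds <- c(); trs_raw <- c()
    for (tn in tns) {
      cor_tn <- apply_fbc(tn, baselines[[tn$patient_id]], model, mode = "test")
      for (ch in seq_along(tn$channels)) {
        v <- cor_tn$values[, ch, f_idx]
        trs <- c(trs, as.numeric(optimal_threshold(v, tn$labels)))
        sds <- c(sds, sd(v))
        trs_raw <- c(trs_raw,
                     as.numeric(optimal_threshold(
                       signs[f_idx] * tn$values[, ch, f_idx], tn$labels)))
      }
    }
    # corrected thresholds collapse towards zero relative to the feature
    # spread (0.2 x sd at this 3-patient fixture size; the Tr~aNS regression
    # is estimated from only 12 patient-channel points here) ...
    expect_lt(abs(median(trs)), 0.2 * mean(sds))
    # ... and are far smaller than the uncorrected per-channel thresholds
    expect_lt(abs(median(trs)), 0.25 * abs(median(trs_raw)))
  }
})

test_that("FBC model serializes to CSV and back", {
  tns <- tiny_tensors()
  baselines <- lapply(tns, compute_baseline)
  names(baselines) <- vapply(tns, function(t) t$patient_id, "")
  model <- fit_fbc(tns, baselines)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fbc_model(model, path)
  back <- read_fbc_model(path)
  expect_equal(back$slope, model$slope, tolerance = 1e-10)
  expect_equal(back$feature, model$feature)
})
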