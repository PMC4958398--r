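test_that("patient balancing replicates to Nmax per class and is idempotent", {
  df <- data.frame(
    patient_id = c(rep("a", 8), rep("b", 10)),
    label = c(rep(1, 3), rep(0, 5), rep(1, 5), rep(0, 5)),
    score = rnorm(18))
  bal <- balance_patients(df, seed = 2L)
  counts <- table(bal$patient_id, bal$label)
  expect_true(all(counts[, "1"] == 5))
  expect_true(all(counts[, "0"] == 5))
  # already balanced -> returned unchanged (up to row order)
  bal2 <- balance_patients(bal, seed = 3L)
  expect_equal(nrow(bal2), nrow(bal))
  expect_equal(sort(bal2$score), sort(bal$score))
  # single patient unchanged
  one <- df[df$patient_id == "a", ]
  expect_equal(nrow(balance_patients(one, seed = 1L)), nrow(one))
  expect_error(balance_patients(df[0, ]), "empty")
})

test_that("balancing neutralizes patient duplication (equal weighting)", {
  set.seed(44)
  df <- data.frame(
    patient_id = rep(c("a", "b"), each = 40),
    label = rep(c(rep(1, 10), rep(0, 30)), 2),
    score = c(rnorm(10, 2), rnorm(30), rnorm(10, 1), rnorm(30)))
  base <- mean(vapply(1:20, function(s) {
    bal <- balance_patients(df, seed = s)
    roc_auc(bal$score, bal$label)$auc
  }, 0))
  dup <- rbind(df, df[df$patient_id == "b", ])
  dup_auc <- mean(vapply(1:20, function(s) {
    bal <- balance_patients(dup, seed = 100 + s)
    roc_auc(bal$score, bal$label)$auc
  }, 0))
  expect_lt(abs(base - dup_auc), 0.01)
})

test_that("ROC endpoints and reversal", {
  sep <- c(rnorm(50, 10), rnorm(50, -10))
  lab <- rep(c(1, 0), each = 50)
  expect_equal(roc_auc(sep, lab)$auc, 1)
  expect_equal(roc_auc(-sep, lab)$auc, 0)
  expect_error(roc_auc(sep, rep(1, 100)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise-comparison oracle (with ties)", {
  set.seed(12)
  for (i in 1:10) {
    n <- 150
    scores <- round(rnorm(n), 1)     # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("vertical averaging interpolates and averages sensitivities", {
  r1 <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  same <- vertical_average(list(r1, r1))
  ref <- vertical_average(list(r1))
  expect_equal(same$sensitivity, ref$sensitivity)
  # hand-built curves: sens 0.6 and 0.8 at specificity 0.9 -> mean 0.7
  mk <- function(s) structure(list(thresholds = NA, sensitivity = c(0, s, 1),
                                   specificity = c(1, 0.9, 0), auc = NA),
                              class = "roc_curve")
  av <- vertical_average(list(mk(0.6), mk(0.8)), specificity_grid = c(0.9))
  expect_equal(av$sensitivity, 0.7)
  # averaged AUC lies between the input AUCs
  set.seed(3)
  r2 <- roc_auc(rnorm(100) + rep(c(0, 1.5), 50), rep(c(0, 1), 50))
  r3 <- roc_auc(rnorm(100) + rep(c(0, 0.3), 50), rep(c(0, 1), 50))
  avg <- vertical_average(list(r2, r3))
  expect_gte(avg$auc + 1e-9, min(r2$auc, r3$auc) - 0.02)
  expect_lte(avg$auc - 1e-9, max(r2$auc, r3$auc) + 0.02)
})

test_that("relative gain formula and its edge cases", {
  expect_equal(relative_gain(0.8, 0.9), 50)
  expect_equal(relative_gain(0.73, 0.73), 0)
  expect_equal(relative_gain(0.5, 1.0), 100)
  expect_error(relative_gain(1, 1), "undefined")
})

test_that("event metrics: worked example and brute-force agreement", {
  # 10 epochs of 10 s (stride 10), seizure over epochs 4-6, positives {1,2},{5},{9}
  starts <- seq(0, 90, by = 10)
  dec <- rep(0L, 10); dec[c(1, 2, 5, 9)] <- 1L
  ann <- data.frame(start_s = 30, end_s = 60)
  em <- event_metrics(dec, starts, 10, ann, record_duration_h = 1)
  expect_equal(em$fd_count, 2L)
  expect_equal(em$fd_per_hour, 2)
  expect_equal(em$sdr, 1)
  # all-negative and exact-coverage cases
  em0 <- event_metrics(rep(0L, 10), starts, 10, ann, 1)
  expect_equal(em0$fd_count, 0L); expect_equal(em0$sdr, 0)
  dec2 <- rep(0L, 10); dec2[4:6] <- 1L
  em2 <- event_metrics(dec2, starts, 10, ann, 1)
  expect_equal(em2$fd_count, 0L); expect_equal(em2$sdr, 1)
})

test_that("FD counts match brute-force segment enumeration on random strings", {
  set.seed(99)
  starts <- seq(0, 190, by = 10)
  for (i in 1:300) {
    dec <- rbinom(20, 1, 0.3)
    k <- sample(0:2, 1)
    ann <- if (k == 0) data.frame(start_s = numeric(0), end_s = numeric(0)) else {
      s0 <- sort(sample(seq(0, 180, by = 5), k))
      data.frame(start_s = s0, end_s = s0 + sample(10:40, k, replace = TRUE))
    }
    em <- event_metrics(dec, starts, 10, ann, 1)
    expect_equal(em$fd_count, oracle_fd_count(dec, starts, 10,
                                              seizr:::merge_intervals(ann)))
  }
})

test_that("threshold at target sensitivity is the largest valid threshold", {
  set.seed(4)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.4)
  thr <- threshold_at_sensitivity(scores, labels, 0.80)
  sens <- function(t) mean(scores[labels == 1] >= t)
  expect_gte(sens(thr), 0.80)
  bigger <- sort(unique(scores[scores > thr]))
  if (length(bigger) > 0) expect_lt(sens(bigger[1]), 0.80)
  # separable scores: any threshold at/below the seizure minimum works
  sep <- c(rep(10, 5), rep(-10, 5)); lab <- rep(c(1, 0), each = 5)
  expect_equal(threshold_at_sensitivity(sep, lab, 1.0), 10)
})

test_that("run comparison gates on Shapiro-Wilk then picks t or Wilcoxon", {
  set.seed(15)
  a <- rnorm(10); b <- rnorm(10, 5)
  out <- compare_runs(a, b)
  expect_equal(out$test, "t")
  expect_lt(out$p_value, 0.001)
  same <- compare_runs(a, a + rnorm(10, 0, 1e-8))
  expect_gt(same$p_value, 0.5)
  skw <- exp(rnorm(20, 0, 2))   # heavily skewed -> Wilcoxon branch
  out2 <- compare_runs(skw, exp(rnorm(20, 0.2, 2)))
  expect_equal(out2$test, "wilcoxon")
  expect_error(compare_runs(1:2, 1:5), ">= 3")
})
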