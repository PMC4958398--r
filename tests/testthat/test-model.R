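test_that("training-set assembly honours quotas, caps and determinism", {
  tns <- tiny_tensors()
  spec <- training_set_spec(30, 60, max_seizure_per_patient_channel = 24,
                            seed = 4L)
  ts <- assemble_training_set(tns, spec)
  expect_lte(sum(ts$labels == 1), 30)
  expect_equal(sum(ts$labels == 0), 60)   # plenty of non-seizure FVs available
  # equal per-patient non-seizure quotas (plenty available)
  expect_true(all(table(ts$meta$patient_id[ts$meta$label == 0]) == 20))
  # per-patient per-channel seizure cap
  caps <- table(ts$meta$patient_id[ts$meta$label == 1],
                ts$meta$channel[ts$meta$label == 1])
  expect_true(all(caps <= 24))
  # determinism / seed sensitivity
  ts2 <- assemble_training_set(tns, spec)
  expect_identical(ts$X, ts2$X)
  ts3 <- assemble_training_set(tns, training_set_spec(30, 60, seed = 5L))
  expect_false(identical(ts$X, ts3$X))
  expect_equal(dim(ts3$X), dim(ts$X))
})

test_that("shortfalls take all available FVs and are logged", {
  tns <- tiny_tensors()
  avail <- sum(vapply(tns, function(t) sum(t$labels) * length(t$channels), 0))
  spec <- training_set_spec(10 * avail, 50, seed = 1L)
  ts <- assemble_training_set(tns, spec)
  expect_gt(nrow(ts$shortfall), 0)
  # caps still apply even under shortfall
  caps <- table(ts$meta$patient_id[ts$meta$label == 1],
                ts$meta$channel[ts$meta$label == 1])
  expect_true(all(caps <= 24))
})

test_that("largest-remainder quota allocation sums exactly and is near-equal", {
  q <- seizr:::largest_remainder(10, 3)
  expect_equal(q, c(4L, 3L, 3L))
  expect_equal(sum(seizr:::largest_remainder(4500, 39)), 4500)
  expect_lte(diff(range(seizr:::largest_remainder(4500, 39))), 1)
})

test_that("standardizer: population sd, train-parameter reuse, zero-sd guard", {
  X <- cbind(a = c(1, 3), b = c(2, 2))
  st <- fit_standardizer(X)
  Xs <- apply_standardizer(X, st)
  expect_equal(Xs[, "a"], c(-1, 1), ignore_attr = TRUE)   # population sd = 1
  expect_equal(Xs[, "b"], c(0, 0), ignore_attr = TRUE)    # sd guard 1
  # test rows equal to the training mean map to zero
  Xt <- matrix(st$mean, nrow = 1)
  expect_equal(as.numeric(apply_standardizer(Xt, st)), c(0, 0))
})

test_that("Gaussian SVM separates toy blobs with margin-local support vectors", {
  set.seed(42)
  n <- 50
  X <- rbind(matrix(rnorm(n * 2, 0, 0.5), ncol = 2),
             matrix(rnorm(n * 2, 3, 0.5), ncol = 2))
  y <- rep(c(0, 1), each = n)
  clf <- train_svm(X, y, C = 10, sigma = 2)
  dv <- decision_values(clf, X)
  expect_true(all((dv > 0) == (y == 1)))          # 100% training accuracy
  # support vectors sit closer to the opposite class than non-SVs
  d_other <- vapply(seq_len(2 * n), function(i) {
    min(sqrt(colSums((t(X[y != y[i], ]) - X[i, ])^2)))
  }, 0)
  sv <- seq_len(2 * n) %in% clf$sv_index
  expect_lt(mean(d_other[sv]), mean(d_other[!sv]))
  expect_lt(mean(sv), 0.5)                         # only a subset becomes SV
  expect_error(train_svm(X, rep(1, 2 * n), 10, 2), "both classes")
})

test_that("decision values match an independent SVM solver to 1e-6", {
  skip_if_not_installed("kernlab")
  set.seed(42)
  n <- 25
  X <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
             matrix(rnorm(n * 2, 1.5), ncol = 2))
  y <- rep(c(0, 1), each = n)
  clf <- train_svm(X, y, C = 10, sigma = 2, tolerance = 1e-8)
  dv <- decision_values(clf, X)
  kk <- kernlab::ksvm(X, factor(y), type = "C-svc", kernel = "rbfdot",
                      kpar = list(sigma = 1 / (2 * 2^2)), C = 10,
                      tol = 1e-8, scaled = FALSE)
  dk <- kernlab::predict(kk, X, type = "decision")[, 1]
  if (cor(dv, dk) < 0) dk <- -dk
  expect_lt(max(abs(dv - dk)), 1e-6)
})

test_that("a very wide kernel approaches a linear separator on separable data", {
  set.seed(9)
  n <- 30
  X <- rbind(matrix(rnorm(n * 2, 0, 0.3), ncol = 2),
             matrix(rnorm(n * 2, 2, 0.3), ncol = 2))
  y <- rep(c(0, 1), each = n)
  clf <- train_svm(X, y, C = 100, sigma = 50)
  # linear reference labelling via LDA-like midpoint rule
  w <- colMeans(X[y == 1, ]) - colMeans(X[y == 0, ])
  b <- sum(w * (colMeans(X[y == 1, ]) + colMeans(X[y == 0, ])) / 2)
  lin_lab <- as.integer(X %*% w - b > 0)
  expect_equal(as.integer(decision_values(clf, X) > 0), lin_lab)
})

test_that("grid search picks the constructed optimum and breaks ties low", {
  set.seed(10)
  n <- 40
  X <- rbind(matrix(rnorm(n * 2, 0, 1.2), ncol = 2),
             matrix(rnorm(n * 2, 2, 1.2), ncol = 2))
  y <- rep(c(0, 1), each = n)
  pid <- rep(sprintf("p%d", 1:8), times = 10)
  # single cell returns that cell
  g1 <- grid_search(X, y, pid, C_grid = 20, sigma_grid = 8)
  expect_equal(g1$C, 20); expect_equal(g1$sigma, 8)
  # easily separable data: all cells near-perfect, tie-break -> smallest pair
  Xs <- rbind(matrix(rnorm(n * 2, 0, 0.1), ncol = 2),
              matrix(rnorm(n * 2, 5, 0.1), ncol = 2))
  g2 <- grid_search(Xs, y, pid, C_grid = c(10, 20), sigma_grid = c(4, 5))
  expect_equal(g2$C, 10); expect_equal(g2$sigma, 4)
  # full default grid contains the printed per-scenario optima
  g3 <- grid_search(X, y, pid)
  expect_true(all(vapply(svm_param_presets(), function(p) {
    any(g3$auc_table$C == p[["C"]] & g3$auc_table$sigma == p[["sigma"]])
  }, TRUE)))
})

test_that("support-vector composition fractions are coherent", {
  set.seed(30)
  n <- 40
  # cohort A overlaps more than cohort B -> A contributes more SVs
  XA <- rbind(matrix(rnorm(n * 2, 0, 1.5), ncol = 2),
              matrix(rnorm(n * 2, 1, 1.5), ncol = 2))
  XB <- rbind(matrix(rnorm(n * 2, 6, 0.3), ncol = 2),
              matrix(rnorm(n * 2, 10, 0.3), ncol = 2))
  X <- rbind(XA, XB)
  y <- rep(rep(c(0, 1), each = n), 2)
  prov <- data.frame(cohort = rep(c("A", "B"), each = 2 * n), label = y)
  clf <- train_svm(X, y, C = 10, sigma = 2, provenance = prov)
  comp <- sv_composition(clf)
  expect_equal(sum(comp$by_cohort$sv_fraction), 1)
  fa <- comp$by_cohort$sv_fraction[comp$by_cohort$cohort == "A"]
  expect_gt(fa, 0.5)
  # single-cohort training -> 100% of SVs from that cohort
  clfA <- train_svm(XA, y[1:(2 * n)], C = 10, sigma = 2,
                    provenance = prov[1:(2 * n), ])
  compA <- sv_composition(clfA)
  expect_equal(compA$by_cohort$sv_fraction, 1)
  expect_error(sv_composition(train_svm(X, y, 10, 2)), "provenance")
})
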