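test_that("quadratic SVM separates XOR and flips sign under label swap", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  y <- c(1L, 2L, 2L, 1L)                       # XOR labelling
  m <- train_quadratic_svm(X, y, qsvm_config(C = 100, tol = 1e-8))
  expect_equal(predict(m, X)$class, y)
  # label swap flips every decision value
  m2 <- train_quadratic_svm(X, 3L - y, qsvm_config(C = 100, tol = 1e-8))
  expect_equal(predict(m2, X)$score, -predict(m, X)$score, tolerance = 1e-6)
  expect_error(train_quadratic_svm(X, rep(1L, 4)), "two classes")
})

test_that("SVM decision values agree with the quadprog dual oracle", {
  # n = 12 points in the 15-dimensional quadratic feature space of d = 4:
  # the kernel matrix is positive definite, so the dual solution is unique
  # and the oracle comparison is well-posed
  for (seed in c(7, 19)) {
    toy <- toy_gaussian(n_per_class = 6, d = 4, seed = seed)
    K <- (1 + toy$x %*% t(toy$x))^2
    dec_oracle <- svm_dual_oracle(K, toy$y, C = 1)
    m <- train_quadratic_svm(toy$x, toy$y,
                             qsvm_config(tol = 1e-10, max_iter = 1000000L))
    expect_lt(max(abs(predict(m, toy$x)$score - dec_oracle)), 1e-6)
    # large-margin separable toy: zero training errors
    expect_equal(predict(m, toy$x)$class, toy$y)
  }
})

test_that("narrow NN learns a separable toy and is seed-deterministic", {
  toy <- toy_gaussian(n_per_class = 40, d = 2, sep = 2, seed = 31)
  z <- scale(toy$x)
  cfg <- nnn_config(seed = 5L)
  m <- train_narrow_nn(z, toy$y, cfg)
  expect_gte(mean(predict(m, z)$class == toy$y), 0.95)
  m2 <- train_narrow_nn(z, toy$y, cfg)
  expect_identical(m$W1, m2$W1)
  expect_identical(m$W2, m2$W2)
  # constant-zero input: predictions constant across samples
  mz <- train_narrow_nn(matrix(0, 20, 3), rep(c(1L, 2L), 10), nnn_config(seed = 2L))
  pz <- predict(mz, matrix(0, 7, 3))
  expect_length(unique(pz$class), 1)
  expect_equal(diff(range(pz$score)), 0)
})

test_that("kNN preset classifies by nearest neighbours", {
  toy <- toy_gaussian(n_per_class = 15, d = 3, sep = 2, seed = 41)
  m <- train_classifier(toy$x, toy$y, knn_config(k = 1L))
  expect_equal(predict(m, toy$x)$class, toy$y)   # 1-NN memorizes
  expect_gte(mean(predict(m, toy$x + rnorm(90, sd = 0.2))$class == toy$y), 0.9)
})

test_that("participant folds partition the cohort, stratified and seeded", {
  pts <- data.frame(participant_id = sprintf("P%03d", 1:40),
                    label = rep(c(1L, 2L), 20))
  plan <- participant_folds(pts, n_folds = 10, seed = 3)
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_true(all(table(plan$fold) == 4))
  expect_true(all(table(plan$fold, plan$label) == 2))    # stratified
  expect_identical(plan, participant_folds(pts, 10, seed = 3))
  # leave-one-participant-out when n_folds = participants per class permits
  plan1 <- participant_folds(pts, n_folds = 20, seed = 3)
  expect_true(all(table(plan1$fold) == 2))
  expect_error(participant_folds(pts[1:10, ], n_folds = 10), "n_folds")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(44)
  for (i in 1:20) {
    cm <- c(TP = sample(0:500, 1), FP = sample(0:500, 1),
            TN = sample(0:500, 1), FN = sample(0:500, 1))
    if (sum(cm) == 0) next
    m <- classification_metrics(cm)
    tot <- sum(cm)
    expect_equal(m[["accuracy"]], 100 * (cm[["TP"]] + cm[["TN"]]) / tot,
                 tolerance = 1e-12)
    if (!is.na(m[["f1"]]))
      expect_equal(m[["f1"]],
                   2 * m[["precision"]] * m[["sensitivity"]] /
                     (m[["precision"]] + m[["sensitivity"]]),
                   tolerance = 1e-12)
  }
  perfect <- classification_metrics(c(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unname(perfect), rep(100, 5))
  # zero denominator reported as NA
  expect_true(is.na(classification_metrics(c(TP = 0, FP = 0, TN = 5,
                                             FN = 5))[["precision"]]))
})

test_that("ROC/PR curves: perfect, reversed and uninformative scores", {
  y <- rep(c(1L, 2L), each = 50)
  s_perf <- c(runif(50, 1, 2), runif(50, -2, -1))
  out <- roc_pr_curves(s_perf, y)
  expect_equal(out$roc_auc, 1)
  expect_equal(out$pr_auc, 1)
  # reversing scores maps AUC to 1 - AUC
  set.seed(45)
  s <- rnorm(100) + (y == 1) * 0.8
  expect_equal(roc_pr_curves(-s, y)$roc_auc, 1 - roc_pr_curves(s, y)$roc_auc,
               tolerance = 1e-12)
  # label-independent scores: AUC ~ 0.5
  s0 <- rnorm(100)
  expect_lt(abs(roc_pr_curves(s0, y)$roc_auc - 0.5), 0.2)
  expect_error(roc_pr_curves(s0, rep(1L, 100)), "one class")
})

test_that("run_cv partitions test folds exactly once per segment", {
  fm <- toy_feature_table(n_participants = 24, seg_per_pt = 4, shift = 2.5,
                          seed = 46)
  plan <- participant_folds(fm, n_folds = 3, seed = 46)
  covered <- integer(0)
  for (f in 1:3) {
    idx <- lungsoundr:::cv_fold_rows(fm, plan, f)
    expect_length(intersect(covered, idx$test), 0)
    covered <- c(covered, idx$test)
  }
  expect_setequal(covered, seq_len(nrow(fm)))
  r <- run_cv(fm, plan, qsvm_config(), select_k = 5L, k_neighbors = 4L)
  expect_equal(unname(sum(r$confusion)), nrow(fm))
  expect_gt(r$metrics[["accuracy"]], 85)     # clearly separable toy
})
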