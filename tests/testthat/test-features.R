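test_that("feature combination concatenates verbatim into 15 columns", {
  m <- stats::setNames(rnorm(14), sprintf("mfcc_%02d", 1:14))
  t1 <- c(tqwt_Etotal = -3.2)
  v <- combine_features(m, t1)
  expect_length(v, 15)
  expect_equal(unname(v[1:14]), unname(m))
  expect_equal(v[["tqwt_Etotal"]], -3.2)
  expect_equal(unname(combine_features(m * 0, c(tqwt_Etotal = 0))), numeric(15))
  expect_error(combine_features(numeric(0), t1), "empty")
})

test_that("standardizer fits on selected rows and replays on held-out rows", {
  set.seed(20)
  x <- matrix(rnorm(200, 5, 3), 40)
  colnames(x) <- paste0("f", 1:5)
  std <- fit_standardizer(x)
  z <- apply_standardizer(std, x)
  expect_equal(unname(colMeans(z)), numeric(5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # fit on a subset; held-out transform equals (x - mu_fit)/sd_fit
  fitr <- 1:25
  std2 <- fit_standardizer(x, fitr)
  z2 <- apply_standardizer(std2, x)
  mu <- colMeans(x[fitr, ]); sdv <- apply(x[fitr, ], 2, sd)
  expect_equal(z2[30, ], (x[30, ] - mu) / sdv)
  # held-out rows are not (0, 1) in general — no leakage
  expect_gt(max(abs(colMeans(z2[26:40, ]))), 1e-3)
  # constant column centered and flagged
  xc <- cbind(x, cns = 7)
  stdc <- fit_standardizer(xc)
  expect_true(stdc$constant[["cns"]])
  expect_equal(unname(apply_standardizer(stdc, xc)[, 6]), numeric(40))
})

test_that("relieff matches the brute-force double loop exactly", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 30; p <- 5
    x <- matrix(rnorm(n * p), n)
    colnames(x) <- paste0("f", 1:p)
    y <- rep(c(1L, 2L), length.out = n)
    x[y == 1, 1] <- x[y == 1, 1] + 2      # one informative feature
    got <- relieff(x, y, k_neighbors = 5L)
    want <- relieff_brute(x, y, 5L)
    expect_equal(unname(got$weights), want, tolerance = 1e-12)
  }
})

test_that("relieff ranks, ties and symmetries behave", {
  set.seed(22)
  n <- 24
  y <- rep(c(1L, 2L), each = n / 2)
  sep <- c(rnorm(n / 2, 3, 0.3), rnorm(n / 2, -3, 0.3))
  noise <- rnorm(n)
  x <- cbind(sep = sep, noise = noise, const = 1)
  r <- relieff(x, y, k_neighbors = 5L)
  expect_equal(r$feature_names[r$ranking[1]], "sep")
  expect_equal(unname(r$weights[["const"]]), 0)          # constant => exactly 0
  expect_true(all(r$weights >= -1 & r$weights <= 1))
  # permuting feature order permutes weights identically
  xp <- x[, c(2, 3, 1)]
  rp <- relieff(xp, y, k_neighbors = 5L)
  expect_equal(unname(rp$weights[c("sep", "noise", "const")]),
               unname(r$weights[c("sep", "noise", "const")]))
  expect_error(relieff(x, y, k_neighbors = 20L), "k_neighbors")
  expect_error(relieff(x, rep(1L, n), 3L), "two classes")
})

test_that("top-k selection keeps original column order and validates k", {
  set.seed(23)
  fm <- toy_feature_table()
  std <- fit_standardizer(fm)
  r <- relieff(apply_standardizer(std, fm), fm$label, 5L)
  sel10 <- select_top_k(r, fm, k = 10L)
  expect_length(setdiff(colnames(sel10), c("participant_id", "label",
                                           "site_id", "segment_index")), 10)
  feats <- setdiff(colnames(sel10), c("participant_id", "label", "site_id",
                                      "segment_index"))
  expect_equal(feats, intersect(colnames(fm), feats))   # original order kept
  # k = n keeps everything; k = 1 keeps the max-weight feature
  expect_equal(ncol(select_top_k(r, fm, k = 15L)), ncol(fm))
  expect_equal(setdiff(colnames(select_top_k(r, fm, k = 1L)),
                       c("participant_id", "label", "site_id", "segment_index")),
               r$feature_names[r$ranking[1]])
  expect_error(select_top_k(r, fm, k = 16L), "exceeds")
})

test_that("top-k sweep is leakage-free bookkeeping over requested k", {
  fm <- toy_feature_table(n_participants = 16, seg_per_pt = 4, seed = 24)
  plan <- participant_folds(fm, n_folds = 4, seed = 24)
  ks <- c(1, 3, 15)
  sweep_out <- topk_accuracy_sweep(fm, plan, k_values = ks,
                                   model_config = qsvm_config(),
                                   k_neighbors = 5L)
  expect_equal(sweep_out$k, ks)
  expect_equal(nrow(sweep_out), length(ks))
  # with 3 informative features, k=3 cannot do worse than k=1
  expect_gte(sweep_out$accuracy[2], sweep_out$accuracy[1])
  # k = all features reproduces the no-selection CV accuracy
  full <- run_cv(fm, plan, qsvm_config(), select_k = NULL)
  expect_equal(sweep_out$accuracy[3], full$metrics[["accuracy"]])
})

test_that("permutation importance flags the separating feature, reproducibly", {
  set.seed(25)
  n <- 80
  y <- rep(c(1L, 2L), each = n / 2)
  x <- cbind(sep = c(rnorm(n / 2, 2), rnorm(n / 2, -2)), noise = rnorm(n))
  fit <- train_quadratic_svm(scale(x), y, qsvm_config())
  imp <- permutation_importance(fit, scale(x), y, n_repeats = 10L, seed = 9L)
  expect_equal(names(which.max(imp)), "sep")
  expect_lt(abs(imp[["noise"]]), 5)                      # ignored => drop ~ 0
  imp2 <- permutation_importance(fit, scale(x), y, n_repeats = 10L, seed = 9L)
  expect_identical(imp, imp2)
})

test_that("selection is stable across identical runs on a fixed cohort", {
  fm <- small_cohort_features(n_per_class = 6, seed = 77)
  plan <- participant_folds(fm, n_folds = 3, seed = 77)
  r1 <- run_cv(fm, plan, qsvm_config(), select_k = 10L, k_neighbors = 5L)
  r2 <- run_cv(fm, plan, qsvm_config(), select_k = 10L, k_neighbors = 5L)
  expect_identical(r1$selected_features, r2$selected_features)
  expect_identical(r1$metrics, r2$metrics)
})
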