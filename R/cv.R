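# Participant-level stratified cross-validation and the evaluation panel.
#
# Folds are assigned by participant (stratified by class) so that no
# participant's segments are split across training and test; on the default
# cohort each of the 10 folds holds 12 participants = 360 test segments
# against 3240 training segments.

#' Participant-level stratified fold assignment
#'
#' Seeded shuffle within each class, then round-robin assignment to folds.
#'
#' @param participants data.frame with `participant_id` and `label` columns
#'   (one row per participant), or a feature/manifest data.frame from which
#'   the unique pairs are taken
#' @param n_folds number of folds (default 10)
#' @param seed RNG seed
#' @return a `cv_plan` data.frame: `participant_id`, `label`, `fold`
#' @export
participant_folds <- function(participants, n_folds = 10L, seed = 1L) {
  pts <- unique(participants[, c("participant_id", "label")])
  stopifnot(is_count(n_folds), nrow(pts) >= n_folds)
  if (any(table(pts$label) < n_folds))
    stop("each class needs at least n_folds participants")
  set.seed(seed)
  pts$fold <- NA_integer_
  for (cl in sort(unique(pts$label))) {
    idx <- which(pts$label == cl)
    idx <- idx[sample(length(idx))]
    pts$fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  pts <- pts[order(pts$participant_id), ]
  rownames(pts) <- NULL
  class(pts) <- c("cv_plan", "data.frame")
  pts
}

cv_fold_rows <- function(fm, plan, fold) {
  test_ids <- plan$participant_id[plan$fold == fold]
  test <- which(fm$participant_id %in% test_ids)
  list(train = setdiff(seq_len(nrow(fm)), test), test = test)
}

#' Classification metric panel from confusion counts
#'
#' Asthma (label 1) is the positive class.  Percentages; `NA` where a
#' denominator is zero.
#'
#' @param cm named vector or list with `TP`, `FP`, `TN`, `FN`
#' @return named numeric vector: accuracy, precision, sensitivity,
#'   specificity, f1 (percent)
#' @export
classification_metrics <- function(cm) {
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; tn <- cm[["TN"]]; fn <- cm[["FN"]]
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  div <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- div(tp + tn, tp + fp + tn + fn)
  prec <- div(tp, tp + fp)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  100 * c(accuracy = acc, precision = prec, sensitivity = sens,
          specificity = spec, f1 = f1)
}

#' ROC and precision-recall curves
#'
#' Threshold sweep over the unique scores; ROC-AUC by the trapezoidal rule,
#' PR-AUC by step summation (no interpolation).
#'
#' @param scores continuous classifier scores, larger = more positive
#' @param labels true labels; `positive` marks the positive class
#' @param positive positive-class label value (default 1, asthma)
#' @return list with `roc` (data.frame fpr/tpr), `roc_auc`, `pr`
#'   (data.frame recall/precision), `pr_auc`
#' @export
roc_pr_curves <- function(scores, labels, positive = 1) {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("labels contain only one class")
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]; s <- scores[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- c(diff(s) != 0, TRUE)        # collapse tied scores to one threshold
  tp <- tp[last]; fp <- fp[last]
  P <- sum(pos); N <- length(pos) - P
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  roc_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  pr_auc <- sum(diff(c(0, recall)) * precision)
  list(roc = data.frame(fpr = fpr, tpr = tpr), roc_auc = roc_auc,
       pr = data.frame(recall = recall, precision = precision),
       pr_auc = pr_auc)
}

confusion_counts <- function(pred, truth, positive = 1) {
  c(TP = sum(pred == positive & truth == positive),
    FP = sum(pred == positive & truth != positive),
    TN = sum(pred != positive & truth != positive),
    FN = sum(pred != positive & truth == positive))
}

#' Run participant-level cross-validation
#'
#' Per fold: fit the standardizer and ReliefF selection on the training rows
#' only, train each requested classifier, and evaluate on the held-out
#' participants.  Confusion counts are aggregated over folds; metrics are
#' reported both on the aggregate and as per-fold panels.
#'
#' @param fm feature data.frame from [extract_features()] /
#'   [cohort_feature_matrix()]
#' @param plan a `cv_plan` from [participant_folds()]; must cover every
#'   participant in `fm`
#' @param model_configs a `model_config` or list of them (evaluated on the
#'   same per-fold features, so selection is computed once per fold)
#' @param select_k number of ReliefF-selected features (`NULL` = all)
#' @param k_neighbors ReliefF neighbor count
#' @return an `eval_report` (single config) or named list of them
#' @export
run_cv <- function(fm, plan, model_configs = qsvm_config(), select_k = 10L,
                   k_neighbors = 10L) {
  single <- inherits(model_configs, "model_config")
  if (single) model_configs <- list(model_configs)
  if (is.null(names(model_configs)) || any(names(model_configs) == ""))
    names(model_configs) <- vapply(model_configs, function(m) m$type, "")
  missing_pts <- setdiff(unique(fm$participant_id), plan$participant_id)
  if (length(missing_pts))
    stop("plan does not cover participants: ", paste(missing_pts, collapse = ", "))
  folds <- sort(unique(plan$fold))
  acc <- lapply(model_configs, function(m)
    list(pred = integer(nrow(fm)), score = numeric(nrow(fm)),
         per_fold = vector("list", length(folds))))
  selected <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    idx <- cv_fold_rows(fm, plan, folds[fi])
    if (!length(idx$test)) next
    std <- fit_standardizer(fm, idx$train)
    z <- apply_standardizer(std, fm)
    ztr <- z[idx$train, , drop = FALSE]
    zte <- z[idx$test, , drop = FALSE]
    ytr <- fm$label[idx$train]
    if (!is.null(select_k)) {
      rf <- relieff(ztr, ytr, k_neighbors)
      sel <- sort(rf$ranking[seq_len(select_k)])
      ztr <- ztr[, sel, drop = FALSE]
      zte <- zte[, sel, drop = FALSE]
      selected[[fi]] <- rf$feature_names[sel]
    }
    for (mi in seq_along(model_configs)) {
      fit <- train_classifier(ztr, ytr, model_configs[[mi]])
      pr <- predict_classifier(fit, zte)
      acc[[mi]]$pred[idx$test] <- pr$class
      acc[[mi]]$score[idx$test] <- pr$score
      acc[[mi]]$per_fold[[fi]] <-
        classification_metrics(confusion_counts(pr$class, fm$label[idx$test]))
    }
  }
  reports <- lapply(names(model_configs), function(nm) {
    a <- acc[[nm]]
    cm <- confusion_counts(a$pred, fm$label)
    per_fold <- do.call(rbind, a$per_fold)
    curves <- roc_pr_curves(a$score, fm$label)
    structure(list(model = nm, confusion = cm,
                   metrics = classification_metrics(cm),
                   per_fold = data.frame(fold = folds, per_fold),
                   fold_means = colMeans(per_fold, na.rm = TRUE),
                   roc_auc = curves$roc_auc, pr_auc = curves$pr_auc,
                   roc = curves$roc, pr = curves$pr,
                   scores = a$score, predictions = a$pred,
                   labels = fm$label, selected_features = selected,
                   n_segments = nrow(fm)),
              class = "eval_report")
  })
  names(reports) <- names(model_configs)
  if (single) reports[[1]] else reports
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> model=%s  n=%d segments\n", x$model, x$n_segments))
  cat(sprintf("confusion (asthma positive): TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  m <- x$metrics
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  sensitivity %.2f%%  specificity %.2f%%  F1 %.2f%%\n",
              m["accuracy"], m["precision"], m["sensitivity"],
              m["specificity"], m["f1"]))
  cat(sprintf("ROC-AUC %.4f  PR-AUC %.4f\n", x$roc_auc, x$pr_auc))
  invisible(x)
}

# JSON-serializable summary of an eval_report (curves trimmed).
eval_report_summary <- function(x) {
  list(model = x$model, n_segments = x$n_segments,
       confusion = as.list(x$confusion),
       metrics = as.list(round(x$metrics, 2)),
       fold_means = as.list(round(x$fold_means, 2)),
       roc_auc = x$roc_auc, pr_auc = x$pr_auc)
}
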