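# Feature assembly and selection.
#
# A segment's combined vector is [mfcc_01..mfcc_14, tqwt_Etotal] (order fixed).
# The cohort feature matrix is a data.frame with identifier columns
# (participant_id, label, site_id, segment_index) followed by the features.

.ID_COLS <- c("participant_id", "label", "site_id", "segment_index")

#' Combine MFCC and TQWT features of one segment
#'
#' @param mfcc named MFCC vector for the segment
#' @param tqwt_scalar the segment's TQWT scalar summary (or full vector)
#' @return concatenated named numeric vector (15 values by default)
#' @export
combine_features <- function(mfcc, tqwt_scalar) {
  if (!length(mfcc) || !length(tqwt_scalar)) stop("empty feature input")
  c(mfcc, tqwt_scalar)
}

#' Extract the combined feature matrix from segments
#'
#' @param segments list of `segment` objects (post-QC)
#' @param mfcc_cfg an [mfcc_config()]
#' @param tqwt_cfg a [tqwt_config()]
#' @param tqwt_mode `"total_energy"` or `"full"` (see [tqwt_feature_vector()])
#' @return data.frame: identifier columns then feature columns
#' @export
extract_features <- function(segments, mfcc_cfg = mfcc_config(),
                             tqwt_cfg = tqwt_config(),
                             tqwt_mode = "total_energy") {
  stopifnot(length(segments) > 0L)
  fs <- segments[[1L]]$sample_rate
  n_smp <- length(segments[[1L]]$samples)
  flen <- round(mfcc_cfg$frame_length_ms / 1000 * fs)
  H <- mel_filterbank(flen, fs, mfcc_cfg)
  feats <- vapply(segments, function(s) {
    combine_features(
      mfcc_from_frames(frame_signal(s$samples, s$sample_rate, mfcc_cfg), H, mfcc_cfg),
      tqwt_feature_vector(s, tqwt_cfg, mode = tqwt_mode))
  }, FUN.VALUE = numeric(mfcc_cfg$n_coeffs +
                           length(tqwt_feature_vector(segments[[1L]], tqwt_cfg,
                                                      mode = tqwt_mode))))
  ids <- data.frame(
    participant_id = vapply(segments, function(s) s$participant_id, ""),
    label = vapply(segments, function(s) as.integer(s$label), 0L),
    site_id = vapply(segments, function(s) s$site_id, ""),
    segment_index = vapply(segments, function(s) as.integer(s$index), 0L),
    stringsAsFactors = FALSE)
  cbind(ids, as.data.frame(t(feats)))
}

#' Streamed feature matrix for a synthetic cohort
#'
#' Simulates each participant in turn, segments and QC-filters the audio, and
#' extracts features immediately, so the full cohort's audio is never held in
#' memory.  On the default configuration the result is 3600 rows x
#' (4 id + 15 feature) columns.
#'
#' @param config a [synth_cohort_config()]
#' @param mfcc_cfg,tqwt_cfg,tqwt_mode feature settings (see
#'   [extract_features()])
#' @param segment_length seconds per segment
#' @param qc apply [quality_filter()] with default thresholds
#' @return feature matrix data.frame
#' @export
cohort_feature_matrix <- function(config, mfcc_cfg = mfcc_config(),
                                  tqwt_cfg = tqwt_config(),
                                  tqwt_mode = "total_energy",
                                  segment_length = 3, qc = TRUE) {
  pts <- cohort_participants(config)
  out <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    recs <- simulate_participant(config, pts$participant_id[i], pts$label[i])
    segs <- unlist(lapply(recs, segment_recording, segment_length = segment_length),
                   recursive = FALSE)
    if (qc) segs <- quality_filter(segs, band = config$noise_band)$kept
    out[[i]] <- extract_features(segs, mfcc_cfg, tqwt_cfg, tqwt_mode)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

feature_columns <- function(fm) setdiff(colnames(fm), .ID_COLS)

#' Fit a z-score standardizer on selected rows
#'
#' Means and SDs come from `fit_rows` only, so the transform can be replayed
#' on held-out rows without leakage.  Constant columns (SD = 0) are centered
#' only and flagged.
#'
#' @param x numeric matrix or feature data.frame (feature columns only are
#'   used for a data.frame)
#' @param fit_rows row indices used to estimate the parameters (default all)
#' @return a `standardizer` with `center`, `scale`, `constant`
#' @export
fit_standardizer <- function(x, fit_rows = seq_len(nrow(x))) {
  stopifnot(length(fit_rows) > 0L)
  m <- as.matrix(if (is.data.frame(x)) x[, feature_columns(x), drop = FALSE] else x)
  mu <- colMeans(m[fit_rows, , drop = FALSE])
  sdv <- apply(m[fit_rows, , drop = FALSE], 2, sd)
  constant <- sdv == 0 | !is.finite(sdv)
  sdv[constant] <- 1
  structure(list(center = mu, scale = sdv, constant = constant),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std a `standardizer` from [fit_standardizer()]
#' @param x matrix or feature data.frame to transform
#' @return numeric matrix of z-scores `(x - center) / scale`
#' @export
apply_standardizer <- function(std, x) {
  m <- as.matrix(if (is.data.frame(x)) x[, feature_columns(x), drop = FALSE] else x)
  stopifnot(ncol(m) == length(std$center))
  sweep(sweep(m, 2, std$center), 2, std$scale, "/")
}

#' ReliefF feature weights
#'
#' Every sample serves as an anchor (m = n).  For each anchor, the
#' `k_neighbors` nearest same-class hits and nearest other-class misses
#' (Manhattan distance on range-normalized features, index-order tie-break)
#' update each feature's weight by mean |diff to misses| - mean |diff to
#' hits|; weights are averaged over anchors and lie in \[-1, 1\].  A feature
#' constant across all samples gets weight exactly 0.
#'
#' @param x numeric matrix or feature data.frame
#' @param labels binary labels (two distinct values), length `nrow(x)`
#' @param k_neighbors hits/misses per anchor (default 10)
#' @return a `relieff_result`: `weights`, `ranking` (descending weight,
#'   ties by lower index), `k_neighbors`, `feature_names`
#' @export
relieff <- function(x, labels, k_neighbors = 10L) {
  m <- as.matrix(if (is.data.frame(x)) x[, feature_columns(x), drop = FALSE] else x)
  labels <- as.vector(labels)
  stopifnot(nrow(m) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("relieff requires exactly two classes")
  n <- nrow(m)
  if (min(table(labels)) < k_neighbors + 1L)
    stop("each class needs at least k_neighbors + 1 samples")
  rng <- apply(m, 2, function(col) diff(range(col)))
  ok <- rng > 0
  z <- m
  z[, ok] <- sweep(m[, ok, drop = FALSE], 2, rng[ok], "/")
  z[, !ok] <- 0  # constant features contribute no distance and no weight
  D <- as.matrix(stats::dist(z, method = "manhattan"))
  w <- numeric(ncol(m))
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- same[same != i]
    diff_cls <- which(labels != labels[i])
    hits <- same[order(D[i, same])][seq_len(k_neighbors)]
    misses <- diff_cls[order(D[i, diff_cls])][seq_len(k_neighbors)]
    dh <- abs(sweep(z[hits, , drop = FALSE], 2, z[i, ]))
    dm <- abs(sweep(z[misses, , drop = FALSE], 2, z[i, ]))
    w <- w + colMeans(dm) - colMeans(dh)
  }
  w <- w / n
  ranking <- order(-w, seq_along(w))
  structure(list(weights = stats::setNames(w, colnames(m)),
                 ranking = ranking, k_neighbors = as.integer(k_neighbors),
                 feature_names = colnames(m)),
            class = "relieff_result")
}

#' @export
print.relieff_result <- function(x, ...) {
  cat("<relieff_result> k =", x$k_neighbors, "\n")
  print(round(x$weights[x$ranking], 4))
  invisible(x)
}

#' Restrict a feature matrix to the top-k ReliefF features
#'
#' Original column order is retained within the selection.
#'
#' @param result a `relieff_result`
#' @param x matrix or feature data.frame the result was fitted for
#' @param k number of features to keep
#' @return `x` restricted to the selected feature columns (id columns kept
#'   for a data.frame)
#' @export
select_top_k <- function(result, x, k = 10L) {
  nf <- length(result$weights)
  if (k > nf) stop("k exceeds the number of features (", nf, ")")
  sel <- sort(result$ranking[seq_len(k)])  # original order within selection
  keep <- result$feature_names[sel]
  if (is.data.frame(x)) x[, c(intersect(.ID_COLS, colnames(x)), keep), drop = FALSE]
  else x[, sel, drop = FALSE]
}

#' Cross-validated accuracy versus number of selected features
#'
#' For each fold, standardization and ReliefF are fitted on the training rows
#' only (no selection leakage); accuracy is then evaluated for each `k`.
#'
#' @param fm feature data.frame (see [extract_features()])
#' @param plan a `cv_plan` from [participant_folds()]
#' @param k_values numbers of top features to evaluate
#' @param model_config classifier settings, e.g. [qsvm_config()]
#' @param k_neighbors ReliefF neighbor count
#' @return data.frame with columns `k`, `accuracy` (percent, fold-aggregated)
#' @export
topk_accuracy_sweep <- function(fm, plan, k_values = seq_len(15),
                                model_config = qsvm_config(),
                                k_neighbors = 10L) {
  correct <- stats::setNames(numeric(length(k_values)), k_values)
  total <- 0
  for (f in sort(unique(plan$fold))) {
    idx <- cv_fold_rows(fm, plan, f)
    std <- fit_standardizer(fm, idx$train)
    ztr <- apply_standardizer(std, fm)[idx$train, , drop = FALSE]
    zte <- apply_standardizer(std, fm)[idx$test, , drop = FALSE]
    rf <- relieff(ztr, fm$label[idx$train], k_neighbors)
    total <- total + length(idx$test)
    for (i in seq_along(k_values)) {
      sel <- sort(rf$ranking[seq_len(k_values[i])])
      fit <- train_classifier(ztr[, sel, drop = FALSE], fm$label[idx$train],
                              model_config)
      pred <- predict_classifier(fit, zte[, sel, drop = FALSE])$class
      correct[i] <- correct[i] + sum(pred == fm$label[idx$test])
    }
  }
  data.frame(k = k_values, accuracy = 100 * correct / total)
}

#' Permutation feature importance
#'
#' Mean accuracy drop over `n_repeats` seeded permutations of each feature
#' column, against the unpermuted baseline.
#'
#' @param model a fitted classifier (from [train_classifier()] or the
#'   specific trainers)
#' @param x numeric matrix of evaluation features (same columns the model was
#'   trained on)
#' @param labels true labels
#' @param n_repeats permutations per feature
#' @param seed RNG seed
#' @return named numeric vector of mean accuracy drops (percentage points)
#' @export
permutation_importance <- function(model, x, labels, n_repeats = 10L, seed = 1L) {
  x <- as.matrix(x)
  base <- mean(predict_classifier(model, x)$class == labels)
  set.seed(seed)
  drops <- vapply(seq_len(ncol(x)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample(nrow(x)), j]
      base - mean(predict_classifier(model, xp)$class == labels)
    }, 0))
  }, 0)
  stats::setNames(100 * drops, colnames(x))
}
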