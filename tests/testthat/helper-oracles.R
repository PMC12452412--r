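# Shared fixtures and independent oracles for the test suite.

# Brute-force ReliefF: literal double loop over anchors and neighbours,
# written independently of the package implementation (no dist(), no sweep()).
relieff_brute <- function(x, labels, k) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  z <- x
  for (j in seq_len(p)) {
    r <- max(x[, j]) - min(x[, j])
    z[, j] <- if (r > 0) x[, j] / r else 0
  }
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    s <- 0
    for (j in seq_len(p)) s <- s + abs(z[a, j] - z[b, j])
    d[a, b] <- s; d[b, a] <- s
  }
  w <- numeric(p)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    oth <- which(labels != labels[i])
    hits <- same[order(d[i, same], same)][1:k]
    miss <- oth[order(d[i, oth], oth)][1:k]
    for (j in seq_len(p)) {
      dh <- 0; dm <- 0
      for (h in hits) dh <- dh + abs(z[i, j] - z[h, j])
      for (m in miss) dm <- dm + abs(z[i, j] - z[m, j])
      w[j] <- w[j] + dm / k - dh / k
    }
  }
  w / n
}

# Two well-separated Gaussian clouds; quadratic-kernel matrix is positive
# definite when n < (d+1)(d+2)/2 fails to hold... kept small and
# well-conditioned for the dual-solution oracle.
toy_gaussian <- function(n_per_class = 10, d = 4, sep = 1.5, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d, sep), n_per_class, d),
             matrix(rnorm(n_per_class * d, -sep), n_per_class, d))
  list(x = x, y = rep(c(1L, 2L), each = n_per_class))
}

# Reference dual solution via quadprog on a precomputed kernel matrix.
svm_dual_oracle <- function(K, y01, C = 1, ridge = 1e-10) {
  yy <- ifelse(y01 == sort(unique(y01))[1], 1, -1)
  n <- nrow(K)
  qp <- quadprog::solve.QP(K * outer(yy, yy) + diag(ridge, n), rep(1, n),
                           cbind(yy, diag(n), -diag(n)),
                           c(0, rep(0, n), rep(-C, n)), meq = 1)
  a <- qp$solution
  f <- as.numeric(K %*% (a * yy))
  free <- which(a > 1e-7 & a < C - 1e-7)
  f + mean(yy[free] - f[free])
}

# Small in-memory cohort for pipeline tests: returns a feature matrix.
small_cohort_features <- function(n_per_class = 8, snr_db = 0, seed = 11,
                                  site_count = 2L, site_duration = 6) {
  cfg <- synth_cohort_config(n_asthma = n_per_class, n_healthy = n_per_class,
                             site_count = site_count,
                             site_duration = site_duration,
                             wheeze_snr_db = snr_db, seed = seed)
  cohort_feature_matrix(cfg)
}

# Synthetic (non-audio) feature table with `n_inf` informative and `n_noise`
# pure-noise columns, grouped into pseudo-participants.
toy_feature_table <- function(n_participants = 20, seg_per_pt = 4, n_inf = 3,
                              n_noise = 12, shift = 2, seed = 5) {
  set.seed(seed)
  n <- n_participants * seg_per_pt
  label <- rep(rep(c(1L, 2L), length.out = n_participants), each = seg_per_pt)
  x <- matrix(rnorm(n * (n_inf + n_noise)), n)
  x[label == 1, seq_len(n_inf)] <- x[label == 1, seq_len(n_inf)] + shift
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  cbind(data.frame(participant_id = rep(sprintf("P%03d", seq_len(n_participants)),
                                        each = seg_per_pt),
                   label = label,
                   site_id = "S1",
                   segment_index = rep(seq_len(seg_per_pt), n_participants),
                   stringsAsFactors = FALSE),
        as.data.frame(x))
}
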