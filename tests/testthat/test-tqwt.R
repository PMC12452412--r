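test_that("TQWT round trip is exact over the (Q, r, J) grid", {
  set.seed(10)
  for (Q in c(1, 2, 4)) for (r in c(3, 4)) for (J in c(4, 8)) {
    x <- rnorm(512)
    cfg <- tqwt_config(Q, r, J)
    sb <- tqwt_decompose(x, cfg)
    expect_length(sb, J + 1)
    xr <- tqwt_reconstruct(sb)
    expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
  }
})

test_that("TQWT energy ratio to the input is constant per config", {
  set.seed(11)
  cfg <- tqwt_config(2, 3, 6L)
  ratios <- replicate(8, {
    x <- rnorm(600)
    sb <- tqwt_decompose(x, cfg)
    total_energy(vapply(sb, subband_energy, 0)) / sum(x^2)
  })
  expect_lt(max(abs(ratios - ratios[1])), 1e-6 * ratios[1])
})

test_that("decomposition is linear, zero maps to zero, depth is guarded", {
  cfg <- tqwt_config(1, 3, 5L)
  z <- tqwt_decompose(numeric(256), cfg)
  expect_true(all(vapply(z, function(s) all(s == 0), TRUE)))
  set.seed(12)
  a <- rnorm(256); b <- rnorm(256)
  sa <- tqwt_decompose(a, cfg); sb <- tqwt_decompose(b, cfg)
  sab <- tqwt_decompose(2 * a - b, cfg)
  for (j in seq_along(sa))
    expect_equal(sab[[j]], 2 * sa[[j]] - sb[[j]], tolerance = 1e-10)
  # reconstruction linearity
  expect_equal(tqwt_reconstruct(sab), 2 * a - b, tolerance = 1e-10)
  # too-deep J errors and names the feasible maximum
  jmax <- tqwt_max_levels(64, 1, 3)
  expect_error(tqwt_decompose(numeric(64), tqwt_config(1, 3, jmax + 1L)),
               as.character(jmax))
  expect_error(tqwt_decompose(numeric(65), cfg), "even")
  # config mismatch on reconstruction
  expect_error(tqwt_reconstruct(tqwt_decompose(rnorm(256), cfg),
                                tqwt_config(1, 3, 4L)),
               "match")
})

test_that("a pure tone lands in the band(s) whose passband contains it", {
  fs <- 4000; n <- 8000
  cfg <- tqwt_config(Q = 4, r = 3, J = 14L)
  edges <- tqwt_band_edges(cfg, fs)
  # 1800 Hz sits in band 1's flat (unit-gain) region: >= 80% in that band.
  # (Only band 1 has a flat region in this oversampled bank; interior bands
  # share their transition energy with a neighbour by construction.)
  x1 <- sin(2 * pi * 1800 * (0:(n - 1)) / fs)
  E1 <- vapply(tqwt_decompose(x1, cfg), subband_energy, 0)
  expect_equal(which.max(E1), 1L)
  expect_gt(E1[1] / sum(E1), 0.8)
  # 300 Hz (exact DFT bin) is shared between the two adjacent bands whose
  # supports contain it; together they hold >= 80% of the energy
  x <- sin(2 * pi * 300 * (0:(n - 1)) / fs)
  E <- vapply(tqwt_decompose(x, cfg), subband_energy, 0)
  top2 <- order(E, decreasing = TRUE)[1:2]
  expect_equal(sort(top2), sort(top2)[1] + 0:1)          # adjacent bands
  for (b in top2) {
    expect_lte(edges$f_low[edges$band == b], 300)
    expect_gte(edges$f_high[edges$band == b], 300)
  }
  expect_gt(sum(E[top2]) / sum(E), 0.8)
})

test_that("sub-band descriptors match their definitions", {
  # energy / total energy
  expect_equal(subband_energy(numeric(5)), 0)
  expect_equal(subband_energy(c(1, numeric(4))), 1)
  set.seed(13)
  E <- runif(9)
  expect_equal(total_energy(E), sum(E))
  # stats: constant and {1,-1}; brute-force agreement on random data
  expect_equal(subband_stats(rep(3, 4)), c(mean = 3, var = 0))
  expect_equal(subband_stats(c(1, -1)), c(mean = 0, var = 1))
  s <- rnorm(101)
  expect_equal(subband_stats(s)[["var"]], sum((s - sum(s) / 101)^2) / 101,
               tolerance = 1e-12)
  expect_error(subband_stats(numeric(0)), "empty")
  # entropy: degenerate, uniform, bounds
  expect_equal(shannon_entropy(c(0, 0, 5, 0)), 0)
  expect_equal(shannon_entropy(rep(-2, 16)), log(16))
  for (i in 1:10) {
    v <- rnorm(64)
    h <- shannon_entropy(v)
    expect_gte(h, 0); expect_lte(h, log(64) + 1e-12)
  }
  expect_equal(shannon_entropy(numeric(8)), 0)
  # peak amplitude and P^2 <= E
  expect_equal(max_amplitude(c(-3, 2)), 3)
  expect_equal(max_amplitude(numeric(4)), 0)
  v <- rnorm(32)
  expect_lte(max_amplitude(v)^2, subband_energy(v))
  expect_error(max_amplitude(numeric(0)), "empty")
})

test_that("center frequency formula is verbatim and monotone", {
  expect_equal(center_frequency(1, 0, 2000), 1000)
  f <- center_frequency(1:12, 100, 2000)
  expect_true(all(diff(f) < 0))
  expect_equal(center_frequency(40, 100, 2000), 100, tolerance = 1e-6)
  expect_error(center_frequency(1, 10, 5))
})

test_that("TQWT feature vector: modes, zero segment, gain law", {
  fs <- 4000
  set.seed(14)
  x <- rnorm(3 * fs)
  one <- tqwt_feature_vector(x, sample_rate = fs)
  expect_length(one, 1)
  expect_named(one, "tqwt_Etotal")
  full <- tqwt_feature_vector(x, mode = "full", sample_rate = fs)
  expect_true(all(sprintf("tqwt_%s_1", c("E", "mu", "var", "H", "P", "f")) %in%
                    names(full)))
  # zero segment: every descriptor zero (entropy defined 0)
  z <- tqwt_feature_vector(numeric(3 * fs), mode = "full", sample_rate = fs)
  expect_true(all(z[grep("tqwt_(E|mu|var|H|P)_", names(z))] == 0))
  # doubling amplitude adds log 4 to the scalar summary
  expect_equal(tqwt_feature_vector(2 * x, sample_rate = fs)[["tqwt_Etotal"]] -
                 one[["tqwt_Etotal"]], log(4), tolerance = 1e-9)
  # determinism
  expect_identical(tqwt_feature_vector(x, sample_rate = fs), one)
})
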