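# Seeded synthetic respiratory-sound cohorts.
#
# The generator emulates the cohort structure the classification task assumes:
# each participant contributes site_count posterior-thorax recordings of
# site_duration seconds.  Healthy audio is band-limited Gaussian noise
# amplitude-modulated by a breathing envelope; asthma audio additionally
# carries 1-3 narrowband wheeze components gated to the expiratory phase.

#' Configuration for a synthetic respiratory-sound cohort
#'
#' @param n_asthma,n_healthy participant counts per class
#' @param sample_rate sampling rate in Hz (default 4000: covers the
#'   100-1000 Hz wheeze band with margin)
#' @param site_count auscultation sites per participant
#' @param site_duration seconds recorded per site
#' @param breathing_rate nominal breaths/min; jittered +-10% per participant
#' @param wheeze_freq_range Hz interval wheeze fundamentals are drawn from
#' @param wheeze_snr_db wheeze power relative to the expiratory-phase
#'   background, in dB (`-Inf` disables the wheeze entirely)
#' @param noise_band Hz interval of the band-limited breathing noise
#' @param seed master seed; every participant stream is derived from it
#' @return a `synth_cohort_config` list
#' @export
synth_cohort_config <- function(n_asthma = 60L, n_healthy = 60L,
                                sample_rate = 4000L, site_count = 6L,
                                site_duration = 15, breathing_rate = 15,
                                wheeze_freq_range = c(100, 1000),
                                wheeze_snr_db = 0, noise_band = c(60, 1200),
                                seed = 1L) {
  stopifnot(is_count(n_asthma, 0L), is_count(n_healthy, 0L),
            is_count(sample_rate), is_count(site_count),
            is_scalar_num(site_duration), site_duration > 0,
            is_scalar_num(breathing_rate), breathing_rate > 0,
            length(wheeze_freq_range) == 2L, length(noise_band) == 2L)
  if (wheeze_freq_range[2] >= sample_rate / 2)
    stop("wheeze_freq_range upper bound must be below the Nyquist frequency")
  if (noise_band[1] < 0 || noise_band[2] > sample_rate / 2 ||
      noise_band[1] >= noise_band[2])
    stop("noise_band must lie within [0, sample_rate/2]")
  structure(list(n_asthma = as.integer(n_asthma),
                 n_healthy = as.integer(n_healthy),
                 sample_rate = as.integer(sample_rate),
                 site_count = as.integer(site_count),
                 site_duration = site_duration,
                 breathing_rate = breathing_rate,
                 wheeze_freq_range = as.numeric(wheeze_freq_range),
                 wheeze_snr_db = wheeze_snr_db,
                 noise_band = as.numeric(noise_band),
                 seed = as.integer(seed)),
            class = "synth_cohort_config")
}

# Breathing phase in cycles: one unit = one full inspiration+expiration.
breathing_phase <- function(n, rate, sample_rate, phase0 = 0) {
  (phase0 + (seq_len(n) - 1) / sample_rate * rate / 60) %% 1
}

#' Breathing amplitude envelope
#'
#' Raised-cosine half-cycle humps: one inspiratory and one expiratory hump per
#' breath cycle (`sin^2(2*pi*phase)`), values in \[0, 1\], period `60/rate` s.
#'
#' @param duration seconds
#' @param rate breaths per minute (> 0)
#' @param sample_rate Hz
#' @param phase0 initial phase in cycles
#' @return numeric vector of length `duration * sample_rate`
#' @export
breathing_envelope <- function(duration, rate, sample_rate, phase0 = 0) {
  if (!is_scalar_num(rate) || rate <= 0) stop("rate must be positive")
  n <- round(duration * sample_rate)
  p <- breathing_phase(n, rate, sample_rate, phase0)
  sin(2 * pi * p)^2
}

#' Expiratory gate
#'
#' TRUE over the expiratory half of each breath cycle (phase in \[0.5, 1)).
#'
#' @inheritParams breathing_envelope
#' @return logical vector of length `duration * sample_rate`
#' @export
expiratory_gate <- function(duration, rate, sample_rate, phase0 = 0) {
  if (!is_scalar_num(rate) || rate <= 0) stop("rate must be positive")
  n <- round(duration * sample_rate)
  breathing_phase(n, rate, sample_rate, phase0) >= 0.5
}

# Gaussian noise band-passed to [band[1], band[2]] via a frequency-domain mask
# with raised-cosine transitions of `transition` Hz.
bandpass_noise <- function(n, sample_rate, band, transition = 20) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) / n * sample_rate
  f <- pmin(f, sample_rate - f)  # fold to [0, fs/2]
  mask <- rep(0, n)
  mask[f >= band[1] & f <= band[2]] <- 1
  lo <- f > band[1] - transition & f < band[1]
  mask[lo] <- 0.5 * (1 - cos(pi * (f[lo] - band[1] + transition) / transition))
  hi <- f > band[2] & f < band[2] + transition
  mask[hi] <- 0.5 * (1 + cos(pi * (f[hi] - band[2]) / transition))
  Re(fft(X * mask, inverse = TRUE)) / n
}

# Smooth a binary gate with raised-cosine onset/offset ramps (<= ramp_s each
# side) so gated components start and stop without clicks.
smooth_gate <- function(gate, sample_rate, ramp_s = 0.05) {
  g <- as.numeric(gate)
  n <- length(g)
  d <- diff(c(0, g, 0))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  for (i in seq_along(starts)) {
    run <- ends[i] - starts[i] + 1L
    m <- min(round(ramp_s * sample_rate), run %/% 4L)
    if (m > 1L) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
      g[starts[i] + seq_len(m) - 1L] <- ramp
      g[ends[i] - seq_len(m) + 1L] <- ramp
    }
  }
  g[seq_len(n)]
}

#' Narrowband wheeze component
#'
#' A sinusoid at `freq` Hz present only where `gate` is TRUE (with short
#' raised-cosine ramps), scaled so that its mean power over the gated samples
#' is `background_power * 10^(snr_db/10)`.
#'
#' @param duration seconds
#' @param sample_rate Hz
#' @param freq wheeze fundamental in (0, sample_rate/2)
#' @param snr_db target power ratio to `background_power`, dB; `-Inf` yields
#'   silence
#' @param gate logical vector (expiratory mask) of length
#'   `duration * sample_rate`
#' @param background_power reference power the SNR is measured against
#' @param phase initial oscillator phase, radians
#' @param fm_depth relative depth of slow sinusoidal frequency modulation
#'   (0 = pure tone; the cohort generator uses 0.08 to emulate the pitch
#'   glide of real wheezes)
#' @param fm_rate modulation rate in Hz
#' @param fm_phase modulation phase, radians
#' @param amplitude scalar or per-sample amplitude weighting applied inside
#'   the gate; the cohort generator passes the breathing envelope here so
#'   wheeze loudness tracks expiratory airflow (keeping the local
#'   wheeze-to-background ratio finite where the envelope vanishes)
#' @return numeric vector of length `duration * sample_rate`
#' @export
wheeze_component <- function(duration, sample_rate, freq, snr_db, gate,
                             background_power = 1, phase = 0,
                             fm_depth = 0, fm_rate = 0.4, fm_phase = 0,
                             amplitude = 1) {
  n <- round(duration * sample_rate)
  stopifnot(length(gate) == n)
  if (is.infinite(snr_db) && snr_db < 0) return(numeric(n))
  if (!is_scalar_num(freq) || freq <= 0 || freq >= sample_rate / 2)
    stop("freq must lie in (0, sample_rate/2)")
  if (!any(gate)) return(numeric(n))
  g <- smooth_gate(gate, sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  # instantaneous frequency f(t) = freq (1 + fm_depth sin(2 pi fm_rate t + fm_phase))
  inst_phase <- 2 * pi * freq *
    (t - fm_depth / (2 * pi * fm_rate) * cos(2 * pi * fm_rate * t + fm_phase))
  w <- sin(inst_phase + phase) * g * amplitude
  p_real <- mean(w[gate]^2)
  if (p_real <= 0) return(numeric(n))
  target <- background_power * 10^(snr_db / 10)
  w * sqrt(target / p_real)
}

# All audio for one participant (site_count recordings), from the stream
# derived from (config$seed, participant_id).  Draw order is fixed; do not
# reorder without bumping the package version.
simulate_participant <- function(config, participant_id, label) {
  set.seed(derive_seed(config$seed, participant_id))
  fs <- config$sample_rate
  n <- round(config$site_duration * fs)
  rate <- config$breathing_rate * runif(1, 0.9, 1.1)
  asthma <- label == 1L
  if (asthma) {
    n_wheeze <- sample(1:3, 1)
    freqs <- runif(n_wheeze, config$wheeze_freq_range[1], config$wheeze_freq_range[2])
  }
  lapply(seq_len(config$site_count), function(s) {
    phase0 <- runif(1)
    env <- breathing_envelope(config$site_duration, rate, fs, phase0)
    x <- bandpass_noise(n, fs, config$noise_band) * env
    if (asthma && is.finite(config$wheeze_snr_db)) {
      gate <- expiratory_gate(config$site_duration, rate, fs, phase0)
      bg_power <- mean(x[gate]^2)
      # split the target wheeze power across the components
      snr_each <- config$wheeze_snr_db - 10 * log10(n_wheeze)
      for (f in freqs)
        x <- x + wheeze_component(config$site_duration, fs, f, snr_each, gate,
                                  background_power = bg_power,
                                  phase = runif(1, 0, 2 * pi),
                                  fm_depth = 0.08,
                                  fm_rate = runif(1, 0.2, 0.6),
                                  fm_phase = runif(1, 0, 2 * pi),
                                  amplitude = env)
    }
    x <- x / max(abs(x)) * 0.9  # peak normalization before 16-bit quantization
    new_recording(x, fs, participant_id = participant_id,
                  site_id = sprintf("S%d", s), label = label)
  })
}

cohort_participants <- function(config) {
  ids <- c(sprintf("A%03d", seq_len(config$n_asthma)),
           sprintf("H%03d", seq_len(config$n_healthy)))
  labels <- c(rep(1L, config$n_asthma), rep(2L, config$n_healthy))
  data.frame(participant_id = ids, label = labels, stringsAsFactors = FALSE)
}

#' Simulate a cohort in memory
#'
#' Convenience wrapper over the participant-level generator; for large cohorts
#' prefer [generate_cohort()] (disk) or [cohort_feature_matrix()] (streaming).
#'
#' @param config a [synth_cohort_config()]
#' @return list with `participants` (data.frame) and `recordings` (list of
#'   `recording` objects, sites nested per participant in order)
#' @export
simulate_cohort <- function(config) {
  pts <- cohort_participants(config)
  recs <- list()
  for (i in seq_len(nrow(pts)))
    recs <- c(recs, simulate_participant(config, pts$participant_id[i], pts$label[i]))
  list(config = config, participants = pts, recordings = recs)
}

#' Generate a synthetic cohort on disk
#'
#' Writes one mono 16-bit PCM WAV per (participant, site) and a manifest CSV
#' (`manifest.csv`) with columns participant_id, label, site_id, path,
#' sample_rate, duration_s.  Identical config and seed reproduce byte-identical
#' output.
#'
#' @param config a [synth_cohort_config()]
#' @param out_dir writable output directory (created if missing)
#' @return the manifest as a data.frame, invisibly; also written to
#'   `file.path(out_dir, "manifest.csv")`
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pts <- cohort_participants(config)
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    recs <- simulate_participant(config, pts$participant_id[i], pts$label[i])
    rows[[i]] <- do.call(rbind, lapply(recs, function(r) {
      path <- file.path(out_dir, sprintf("%s_%s.wav", r$participant_id, r$site_id))
      write_wav(r$samples, path, r$sample_rate)
      data.frame(participant_id = r$participant_id, label = r$label,
                 site_id = r$site_id, path = path,
                 sample_rate = r$sample_rate,
                 duration_s = length(r$samples) / r$sample_rate,
                 stringsAsFactors = FALSE)
    }))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
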