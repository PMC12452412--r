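# Segmentation and quality control.
#
# Recordings are cut into non-overlapping fixed-length clips (default 3 s,
# trailing remainder discarded; no windowing).  QC rejects segments that are
# clipped or whose spectral energy falls mostly outside the analysis band.

#' Cut a recording into non-overlapping segments
#'
#' @param rec a `recording` (see [read_wav()])
#' @param segment_length segment duration in seconds (default 3)
#' @param target_rate if given and different from the recording's rate, the
#'   recording is resampled (FFT method) before segmentation
#' @return list of `segment` objects (possibly empty, with a warning, if the
#'   recording is shorter than one segment); each has `samples`,
#'   `sample_rate`, `participant_id`, `site_id`, `label`, `index`
#' @export
segment_recording <- function(rec, segment_length = 3, target_rate = NULL) {
  stopifnot(inherits(rec, "recording"), segment_length > 0)
  x <- rec$samples
  fs <- rec$sample_rate
  if (!is.null(target_rate) && target_rate != fs) {
    x <- resample_fft(x, fs, target_rate)
    fs <- as.integer(target_rate)
  }
  n_seg <- floor(length(x) / (segment_length * fs))
  if (n_seg < 1L) {
    warning("recording shorter than one segment: ", rec$participant_id,
            "/", rec$site_id)
    return(list())
  }
  len <- round(segment_length * fs)
  lapply(seq_len(n_seg), function(i) {
    structure(list(samples = x[((i - 1L) * len + 1L):(i * len)],
                   sample_rate = fs,
                   participant_id = rec$participant_id,
                   site_id = rec$site_id, label = rec$label,
                   index = i),
              class = "segment")
  })
}

# FFT-based resampling (periodic extension).  Adequate for rate adaptation of
# synthetic fixtures; field recordings would normally share one device rate.
resample_fft <- function(x, from, to) {
  n <- length(x)
  m <- round(n * to / from)
  X <- fft(x)
  Y <- complex(m)
  h <- min(n, m) %/% 2
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h > 1) Y[(m - h + 2):m] <- X[(n - h + 2):n]
  Re(fft(Y, inverse = TRUE)) / n
}

#' Spectral quality control for segments
#'
#' Rejects a segment when its clipped-sample fraction exceeds
#' `clip_fraction_max` ("clipping") or when the fraction of periodogram energy
#' inside `band` falls below `band_energy_min` ("out-of-band energy").
#' Thresholds are inert on clean synthetic audio so printed segment counts are
#' preserved.  Idempotent: re-filtering kept segments removes nothing.
#'
#' @param segments list of `segment` objects
#' @param clip_fraction_max maximum tolerated fraction of samples at full
#'   scale (default 0.01)
#' @param band_energy_min minimum in-band energy fraction (default 0.5)
#' @param band analysis band in Hz (default 60-1200)
#' @return list with `kept` (segments) and `log` (data.frame of rejections:
#'   participant_id, site_id, index, reason)
#' @export
quality_filter <- function(segments, clip_fraction_max = 0.01,
                           band_energy_min = 0.5, band = c(60, 1200)) {
  stopifnot(length(segments) > 0L)
  keep <- logical(length(segments))
  logs <- list()
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    reason <- NA_character_
    clip_frac <- mean(abs(s$samples) >= 0.999)
    if (clip_frac > clip_fraction_max) {
      reason <- "clipping"
    } else {
      p <- Mod(fft(s$samples))^2
      n <- length(p)
      half <- p[1:(n %/% 2 + 1)]
      f <- (seq_along(half) - 1) / n * s$sample_rate
      tot <- sum(half)
      frac <- if (tot > 0) sum(half[f >= band[1] & f <= band[2]]) / tot else 1
      if (frac < band_energy_min) reason <- "out-of-band energy"
    }
    keep[i] <- is.na(reason)
    if (!keep[i])
      logs[[length(logs) + 1L]] <-
        data.frame(participant_id = s$participant_id, site_id = s$site_id,
                   index = s$index, reason = reason, stringsAsFactors = FALSE)
  }
  list(kept = segments[keep],
       log = if (length(logs)) do.call(rbind, logs)
             else data.frame(participant_id = character(), site_id = character(),
                             index = integer(), reason = character(),
                             stringsAsFactors = FALSE))
}
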