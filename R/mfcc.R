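# Mel-frequency cepstral coefficients.
#
# Pipeline per 3-s segment: framing (non-overlapping 30 ms frames, Hamming
# window) -> magnitude spectrum -> Mel filterbank (M = 20 triangles,
# area-normalized) -> log energies -> DCT (indices 1..n_coeffs, DC excluded)
# -> mean over frames.  With area-normalized filters the coefficients are
# invariant to overall waveform gain: a gain moves every log energy by the
# same constant and the cosine sum of a constant over the half-integer grid
# vanishes.

#' MFCC configuration
#'
#' @param frame_length_ms frame length in milliseconds, within \[20, 40\]
#' @param frame_hop_ms hop between frame starts (default = frame length:
#'   non-overlapping)
#' @param n_filters number of triangular Mel filters M
#' @param n_coeffs number of cepstral coefficients retained (DCT indices
#'   1..n_coeffs; the DC term is excluded — overall gain is carried by the
#'   wavelet energy feature instead)
#' @param fmin,fmax filterbank edge frequencies in Hz; `fmax = NULL` means
#'   the Nyquist frequency of the segment
#' @param window `"hamming"` or `"rectangular"`
#' @param log_floor additive floor inside the log, keeps silence finite
#' @return an `mfcc_config` list
#' @export
mfcc_config <- function(frame_length_ms = 30, frame_hop_ms = frame_length_ms,
                        n_filters = 20L, n_coeffs = 14L, fmin = 0,
                        fmax = NULL, window = c("hamming", "rectangular"),
                        log_floor = 1e-12) {
  window <- match.arg(window)
  if (frame_length_ms < 20 || frame_length_ms > 40)
    stop("frame_length_ms must lie in [20, 40]")
  stopifnot(frame_hop_ms > 0, is_count(n_filters), is_count(n_coeffs),
            n_coeffs <= n_filters, fmin >= 0, log_floor > 0)
  structure(list(frame_length_ms = frame_length_ms,
                 frame_hop_ms = frame_hop_ms,
                 n_filters = as.integer(n_filters),
                 n_coeffs = as.integer(n_coeffs),
                 fmin = fmin, fmax = fmax, window = window,
                 log_floor = log_floor),
            class = "mfcc_config")
}

#' Hz to Mel conversion
#'
#' `M(f) = 2595 * log10(1 + f/700)`; monotone, `M(0) = 0`.
#'
#' @param f frequency in Hz (vectorized, must be >= 0)
#' @return Mel value(s)
#' @export
mel_from_hz <- function(f) {
  if (any(f < 0)) stop("frequency must be nonnegative")
  2595 * log10(1 + f / 700)
}

#' @rdname mel_from_hz
#' @param m Mel value(s)
#' @export
hz_from_mel <- function(m) 700 * (10^(m / 2595) - 1)

#' Slice a segment into windowed frames
#'
#' `floor(n_samples / hop)` complete frames; a partial tail is dropped.
#'
#' @param samples numeric vector (one segment)
#' @param sample_rate Hz
#' @param config an [mfcc_config()]
#' @return matrix, `frame_length` rows x `F` columns (one frame per column),
#'   window already applied
#' @export
frame_signal <- function(samples, sample_rate, config = mfcc_config()) {
  flen <- round(config$frame_length_ms / 1000 * sample_rate)
  hop <- round(config$frame_hop_ms / 1000 * sample_rate)
  if (flen > length(samples)) stop("frame longer than segment")
  n_frames <- floor((length(samples) - flen) / hop) + 1L
  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(samples[idx], nrow = flen)
  w <- switch(config$window,
              hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1)),
              rectangular = rep(1, flen))
  frames * w
}

#' DFT magnitude spectrum of a frame
#'
#' Full-length magnitudes `|X[k]|`, k = 0..N-1, satisfying Parseval's
#' identity `sum(y^2) = sum(|X|^2)/N`.
#'
#' @param frame numeric vector
#' @return numeric vector of length `length(frame)`
#' @export
magnitude_spectrum <- function(frame) {
  stopifnot(length(frame) > 0L)
  Mod(fft(frame))
}

#' Triangular Mel filterbank
#'
#' M triangles equally spaced on the Mel axis between `mel(fmin)` and
#' `mel(fmax)`, evaluated at the one-sided FFT bin frequencies and
#' area-normalized (each filter's weights sum to 1).
#'
#' @param n_fft frame length in samples
#' @param sample_rate Hz
#' @param config an [mfcc_config()]
#' @return matrix, `n_filters` rows x `n_fft %/% 2 + 1` columns
#' @export
mel_filterbank <- function(n_fft, sample_rate, config = mfcc_config()) {
  fmax <- config$fmax %||% (sample_rate / 2)
  if (config$fmin >= fmax || fmax > sample_rate / 2)
    stop("need fmin < fmax <= sample_rate/2")
  edges <- hz_from_mel(seq(mel_from_hz(config$fmin), mel_from_hz(fmax),
                           length.out = config$n_filters + 2L))
  bins <- (0:(n_fft %/% 2)) / n_fft * sample_rate
  H <- matrix(0, config$n_filters, length(bins))
  for (m in seq_len(config$n_filters)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- bins >= lo & bins <= mid
    dn <- bins > mid & bins <= hi
    H[m, up] <- (bins[up] - lo) / (mid - lo)
    H[m, dn] <- (hi - bins[dn]) / (hi - mid)
    s <- sum(H[m, ])
    if (s > 0) H[m, ] <- H[m, ] / s
  }
  H
}

#' Log Mel filterbank energies of one frame spectrum
#'
#' `S_m = log(sum_k |X[k]|^2 H_m[k] + eps)`, natural log; finite for any
#' input including digital silence (the floor `eps` guarantees it).
#'
#' @param power one-sided power spectrum, length `ncol(filterbank)`
#' @param filterbank matrix from [mel_filterbank()]
#' @param log_floor additive floor
#' @return numeric vector of length `nrow(filterbank)`
#' @export
log_mel_energies <- function(power, filterbank, log_floor = 1e-12) {
  if (length(power) != ncol(filterbank))
    stop("spectrum length does not match filterbank bins")
  log(as.numeric(filterbank %*% power) + log_floor)
}

#' DCT of the log energies
#'
#' `C(n) = sum_{m=1}^{M} S_m cos(pi * n * (m - 0.5) / M)` for n = 1..n_coeffs
#' (unnormalized; the DC index n = 0 is excluded, so a constant shift of all
#' `S_m` — i.e. waveform gain — leaves every coefficient unchanged).
#'
#' @param S numeric vector of M log energies (or an M x F matrix, one frame
#'   per column)
#' @param n_coeffs number of coefficients
#' @return vector of length `n_coeffs` (or `n_coeffs` x F matrix)
#' @export
dct_coefficients <- function(S, n_coeffs) {
  M <- if (is.matrix(S)) nrow(S) else length(S)
  stopifnot(is_count(n_coeffs), n_coeffs <= M)
  D <- dct_matrix(M, n_coeffs)
  if (is.matrix(S)) D %*% S else as.numeric(D %*% S)
}

dct_matrix <- function(M, n_coeffs) {
  outer(seq_len(n_coeffs), seq_len(M) - 0.5,
        function(n, m) cos(pi * n * m / M))
}

#' Mean MFCC vector of a segment
#'
#' Frames the segment, computes per-frame cepstra, and averages each
#' coefficient over the frames.
#'
#' @param segment a `segment` object, or a numeric vector (then
#'   `sample_rate` must be given)
#' @param config an [mfcc_config()]
#' @param sample_rate Hz, only when `segment` is a bare vector
#' @return named numeric vector `mfcc_01..mfcc_<n_coeffs>`
#' @export
mfcc_mean_vector <- function(segment, config = mfcc_config(), sample_rate = NULL) {
  if (inherits(segment, "segment")) {
    x <- segment$samples; fs <- segment$sample_rate
  } else {
    stopifnot(!is.null(sample_rate))
    x <- as.numeric(segment); fs <- sample_rate
  }
  frames <- frame_signal(x, fs, config)
  H <- mel_filterbank(nrow(frames), fs, config)
  mfcc_from_frames(frames, H, config)
}

# Core shared with the streaming extractor: frames (samples x F), filterbank.
mfcc_from_frames <- function(frames, filterbank, config) {
  n <- nrow(frames)
  P <- Mod(stats::mvfft(frames))^2
  P <- P[1:(n %/% 2 + 1L), , drop = FALSE]
  S <- log(filterbank %*% P + config$log_floor)
  C <- dct_matrix(config$n_filters, config$n_coeffs) %*% S
  out <- rowMeans(C)
  names(out) <- sprintf("mfcc_%02d", seq_len(config$n_coeffs))
  out
}
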