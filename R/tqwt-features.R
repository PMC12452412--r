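# Sub-band descriptors computed on the TQWT decomposition: energy, total
# energy, mean/variance, Shannon entropy (energy-normalized), peak amplitude,
# and the center-frequency bookkeeping formula.

#' Sub-band energy
#'
#' `E_j = sum_n s_j(n)^2`.
#'
#' @param s numeric vector (one sub-band)
#' @return nonnegative scalar
#' @export
subband_energy <- function(s) sum(s^2)

#' Total energy across sub-bands
#'
#' @param energies numeric vector of per-band energies
#' @return `sum(energies)`
#' @export
total_energy <- function(energies) sum(energies)

#' Sub-band mean and population variance
#'
#' @param s numeric vector (one sub-band, non-empty)
#' @return named vector `c(mean, var)`; variance divides by `N_j`
#' @export
subband_stats <- function(s) {
  if (length(s) < 1L) stop("empty sub-band")
  m <- mean(s)
  c(mean = m, var = mean((s - m)^2))
}

#' Shannon entropy of a sub-band
#'
#' Energy-normalized: `p(n) = s(n)^2 / E_j`, `H = -sum p log p` with
#' `0 log 0 = 0`; defined as 0 for an all-zero band.  Bounds:
#' `0 <= H <= log(N_j)`.
#'
#' @param s numeric vector (one sub-band)
#' @return entropy in nats
#' @export
shannon_entropy <- function(s) {
  E <- sum(s^2)
  if (E <= 0) return(0)
  p <- s^2 / E
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sub-band peak amplitude
#'
#' @param s numeric vector (one sub-band, non-empty)
#' @return `max(abs(s))`
#' @export
max_amplitude <- function(s) {
  if (length(s) < 1L) stop("empty sub-band")
  max(abs(s))
}

#' Sub-band center frequency (bookkeeping formula)
#'
#' `f_j = f_low + (f_high - f_low) / 2^j`, implemented verbatim for feature
#' parity; it differs from the transform's analytic band centers, which
#' [tqwt_band_edges()] exposes for diagnostics.
#'
#' @param j band index (>= 1, vectorized)
#' @param f_low,f_high analysis band edges in Hz, `f_low < f_high`
#' @return frequency in Hz, strictly decreasing in j toward `f_low`
#' @export
center_frequency <- function(j, f_low, f_high) {
  stopifnot(f_low < f_high, all(j >= 1))
  f_low + (f_high - f_low) / 2^j
}

#' TQWT feature vector of a segment
#'
#' Decomposes the segment and computes the full descriptor set.  The default
#' combined feature vector uses the single scalar summary
#' `log(E_total + eps)` (mode `"total_energy"`); mode `"full"` returns all
#' per-band descriptors.
#'
#' @param segment a `segment` object or numeric vector (then `sample_rate`
#'   required)
#' @param config a [tqwt_config()]
#' @param mode `"total_energy"` (1 scalar) or `"full"` (per-band descriptors)
#' @param sample_rate Hz, when `segment` is a bare vector
#' @param eps floor inside the log of the scalar summary
#' @return named numeric vector: `tqwt_Etotal`, or per-band
#'   `tqwt_E_j / mu_j / var_j / H_j / P_j / f_j` plus `tqwt_Etotal`
#' @export
tqwt_feature_vector <- function(segment, config = tqwt_config(),
                                mode = c("total_energy", "full"),
                                sample_rate = NULL, eps = 1e-12) {
  mode <- match.arg(mode)
  if (inherits(segment, "segment")) {
    x <- segment$samples; fs <- segment$sample_rate
  } else {
    stopifnot(!is.null(sample_rate))
    x <- as.numeric(segment); fs <- sample_rate
  }
  sb <- tqwt_decompose(x, config)
  E <- vapply(sb, subband_energy, 0)
  Etot <- total_energy(E)
  scalar <- c(tqwt_Etotal = log(Etot + eps))
  if (mode == "total_energy") return(scalar)
  nb <- length(sb)
  stats <- vapply(sb, subband_stats, c(mean = 0, var = 0))
  out <- c(scalar,
           stats::setNames(E, sprintf("tqwt_E_%d", seq_len(nb))),
           stats::setNames(stats["mean", ], sprintf("tqwt_mu_%d", seq_len(nb))),
           stats::setNames(stats["var", ], sprintf("tqwt_var_%d", seq_len(nb))),
           stats::setNames(vapply(sb, shannon_entropy, 0),
                           sprintf("tqwt_H_%d", seq_len(nb))),
           stats::setNames(vapply(sb, max_amplitude, 0),
                           sprintf("tqwt_P_%d", seq_len(nb))),
           stats::setNames(center_frequency(seq_len(nb), 0, fs / 2),
                           sprintf("tqwt_f_%d", seq_len(nb))))
  out
}
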