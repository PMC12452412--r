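# Tunable Q-factor wavelet transform.
#
# Iterated two-channel oversampled filter bank realized in the frequency
# domain with unitary DFTs.  Stage scaling factors: beta = 2/(Q+1),
# alpha = 1 - beta/r.  The low-pass/high-pass split uses the Daubechies
# transition function theta(w) = 0.5(1+cos w) sqrt(2-cos w), which satisfies
# theta(w)^2 + theta(pi-w)^2 = 1, so the bank is a tight frame: perfect
# reconstruction and exact energy preservation hold by construction.

#' TQWT configuration
#'
#' @param Q quality factor (>= 1); higher Q = more oscillatory sub-bands
#' @param r redundancy (> 1); oversampling of the bank
#' @param J number of decomposition levels (>= 1); the output has J
#'   band-pass sub-bands plus one final low-pass
#' @return a `tqwt_config` list with derived `alpha`, `beta`
#' @export
tqwt_config <- function(Q = 1, r = 3, J = 8L) {
  stopifnot(is_scalar_num(Q), Q >= 1, is_scalar_num(r), r > 1, is_count(J))
  beta <- 2 / (Q + 1)
  alpha <- 1 - beta / r
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta <= 1)
  structure(list(Q = Q, r = r, J = as.integer(J), alpha = alpha, beta = beta),
            class = "tqwt_config")
}

# Even sub-band lengths at each level, anchored to the input length so that
# rounding does not accumulate across levels.
tqwt_sizes <- function(n, config) {
  j <- seq_len(config$J)
  list(n0 = 2 * round(config$alpha^j * n / 2),
       n1 = 2 * round(config$beta * config$alpha^(j - 1) * n / 2))
}

#' Maximum feasible decomposition depth for a signal length
#'
#' @param n signal length (even)
#' @param Q,r transform parameters (see [tqwt_config()])
#' @return largest J for which every stage keeps a nonnegative transition
#'   band and at least 4 low-pass samples
#' @export
tqwt_max_levels <- function(n, Q = 1, r = 3) {
  cfg <- tqwt_config(Q, r, 1L)
  jmax <- 0L
  nprev <- n
  repeat {
    j <- jmax + 1L
    n0 <- 2 * round(cfg$alpha^j * n / 2)
    n1 <- 2 * round(cfg$beta * cfg$alpha^(j - 1) * n / 2)
    if (n0 < 4 || n1 < 2 || (n0 + n1 - nprev) / 2 - 1 < 0) break
    jmax <- j
    nprev <- n0
  }
  jmax
}

# Daubechies transition weights over a transition band of T interior points.
theta_weights <- function(T) {
  if (T < 1) return(numeric(0))
  t <- seq_len(T) / (T + 1)
  0.5 * (1 + cos(pi * t)) * sqrt(2 - cos(pi * t))
}

# Analysis split of a unitary DFT X (length n, even) into low-pass DFT
# (length n0) and high-pass DFT (length n1).
tqwt_afb <- function(X, n0, n1) {
  n <- length(X)
  P <- (n - n1) / 2
  T <- (n0 + n1 - n) / 2 - 1
  th <- theta_weights(T)
  ph <- sqrt(pmax(0, 1 - th^2))
  V0 <- complex(n0)
  V0[1] <- X[1]
  if (P >= 1) V0[2:(P + 1)] <- X[2:(P + 1)]
  if (T >= 1) V0[P + 1 + seq_len(T)] <- X[P + 1 + seq_len(T)] * th
  # V0 Nyquist stays 0 (theta is 0 at the stop edge)
  if (n0 >= 4) V0[n0:(n0 / 2 + 2)] <- Conj(V0[2:(n0 / 2)])
  V1 <- complex(n1)
  hw <- c(ph, rep(1, n1 / 2 - T))
  V1[1 + seq_len(n1 / 2)] <- X[P + 1 + seq_len(n1 / 2)] * hw
  if (n1 >= 4) V1[n1:(n1 / 2 + 2)] <- Conj(V1[2:(n1 / 2)])
  list(V0 = V0, V1 = V1)
}

# Synthesis: recombine low-pass DFT V0 and high-pass DFT V1 into a length-n
# DFT, with the same weights (tight frame).
tqwt_sfb <- function(V0, V1, n) {
  n0 <- length(V0); n1 <- length(V1)
  P <- (n - n1) / 2
  T <- (n0 + n1 - n) / 2 - 1
  th <- theta_weights(T)
  ph <- sqrt(pmax(0, 1 - th^2))
  Y <- complex(n)
  Y[1] <- V0[1]
  if (P >= 1) Y[2:(P + 1)] <- V0[2:(P + 1)]
  if (T >= 1)
    Y[P + 1 + seq_len(T)] <- V0[P + 1 + seq_len(T)] * th +
      V1[1 + seq_len(T)] * ph
  hi <- (T + 1):(n1 / 2)
  Y[P + 1 + hi] <- V1[1 + hi]
  Y[n:(n / 2 + 2)] <- Conj(Y[2:(n / 2)])
  Y
}

udft <- function(x) fft(x) / sqrt(length(x))
uidft <- function(X) Re(fft(X, inverse = TRUE)) / sqrt(length(X))

#' Decompose a signal with the TQWT
#'
#' @param x numeric vector of even length
#' @param config a [tqwt_config()]
#' @return a `tqwt_subbands` object: list of J+1 numeric vectors (J band-pass
#'   sub-bands, highest frequency first, then the final low-pass), with the
#'   config and input length attached
#' @export
tqwt_decompose <- function(x, config = tqwt_config()) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n %% 2 != 0) stop("signal length must be even")
  jmax <- tqwt_max_levels(n, config$Q, config$r)
  if (config$J > jmax)
    stop("J = ", config$J, " too deep for length ", n,
         "; maximum feasible J is ", jmax)
  sz <- tqwt_sizes(n, config)
  X <- udft(x)
  bands <- vector("list", config$J + 1L)
  for (j in seq_len(config$J)) {
    sp <- tqwt_afb(X, sz$n0[j], sz$n1[j])
    bands[[j]] <- uidft(sp$V1)
    X <- sp$V0
  }
  bands[[config$J + 1L]] <- uidft(X)
  structure(bands, class = "tqwt_subbands", config = config, n = n)
}

#' Reconstruct a signal from TQWT sub-bands
#'
#' Inverse of [tqwt_decompose()]; exact up to floating-point rounding.
#'
#' @param subbands a `tqwt_subbands` object (or plain list of J+1 vectors)
#' @param config the [tqwt_config()] used for analysis
#' @return numeric vector of the original length
#' @export
tqwt_reconstruct <- function(subbands, config = attr(subbands, "config")) {
  stopifnot(!is.null(config))
  n <- attr(subbands, "n") %||%
    stop("subbands carry no input length; pass a tqwt_subbands object")
  if (length(subbands) != config$J + 1L)
    stop("sub-band count does not match config (J = ", config$J, ")")
  sz <- tqwt_sizes(n, config)
  if (any(vapply(seq_len(config$J), function(j) length(subbands[[j]]), 0L) != sz$n1) ||
      length(subbands[[config$J + 1L]]) != sz$n0[config$J])
    stop("sub-band lengths do not match config: analysis/synthesis config mismatch")
  X <- udft(subbands[[config$J + 1L]])
  for (j in rev(seq_len(config$J))) {
    n_parent <- if (j == 1L) n else sz$n0[j - 1L]
    X <- tqwt_sfb(X, udft(subbands[[j]]), n_parent)
  }
  uidft(X)
}

#' Analytic sub-band frequency supports
#'
#' Band j (1..J) occupies `[(1-beta) a^(j-1), a^(j-1)] * fs/2` with its flat
#' (unit-gain) region `[a^j, a^(j-1)] * fs/2`; band J+1 is the final low-pass
#' `[0, a^J * fs/2]`.  These are the transform's true band edges, exposed for
#' diagnostics alongside the verbatim center-frequency formula
#' ([center_frequency()]).
#'
#' @param config a [tqwt_config()]
#' @param sample_rate Hz
#' @return data.frame with columns band, f_low, f_flat_low, f_high
#' @export
tqwt_band_edges <- function(config, sample_rate) {
  a <- config$alpha; b <- config$beta
  j <- seq_len(config$J)
  ny <- sample_rate / 2
  rbind(data.frame(band = j,
                   f_low = (1 - b) * a^(j - 1) * ny,
                   f_flat_low = a^j * ny,
                   f_high = a^(j - 1) * ny),
        data.frame(band = config$J + 1L, f_low = 0, f_flat_low = 0,
                   f_high = a^config$J * ny))
}
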