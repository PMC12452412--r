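#' @useDynLib lungsoundr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif sd
#' @importFrom utils read.csv write.csv
NULL

.LS_MOD <- 2147483647L  # 2^31 - 1, keeps every derived seed a valid R integer

#' Derive a deterministic child seed from a master seed and a string key
#'
#' Used so that every participant (and every independent stage) gets its own
#' reproducible random stream from one master seed.
#'
#' @param seed master seed (integer)
#' @param key character key, e.g. a participant id
#' @return an integer in [0, 2^31 - 2]
#' @keywords internal
derive_seed <- function(seed, key) {
  stopifnot(length(key) == 1L, is.character(key))
  h <- as.double(seed %% .LS_MOD)
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% .LS_MOD
  as.integer(h)
}

# Polynomial rolling hash of a string, reported as 8 hex digits.  Used to
# stamp a config fingerprint into pipeline artifacts (no digest dependency;
# collision resistance adequate for provenance stamps, not security).
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  sprintf("%08x", derive_seed(104729L, x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
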