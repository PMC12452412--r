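# Minimal RIFF/WAVE (PCM, mono, 16-bit) reader and writer.  No audio package
# ships with this image, and the format needed here is a single fixed profile,
# so the two functions below implement it directly on readBin/writeBin.

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are expected in \[-1, 1\]; values outside are clipped.  Quantization
#' is round-to-nearest on a 2^15 grid, so a write/read round trip preserves
#' samples to within 2^-15.
#'
#' @param samples numeric vector in \[-1, 1\]
#' @param path output file path
#' @param sample_rate sampling rate in Hz
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, path, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) > 0L, is_count(sample_rate))
  if (any(!is.finite(samples))) stop("samples must be finite")
  x <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  data_bytes <- 2L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path
#' @param participant_id,site_id,label optional manifest metadata attached to
#'   the returned recording
#' @return a `recording` object: list with `samples` (numeric, scaled to
#'   \[-1, 1\]), `sample_rate`, and the metadata fields
#' @export
read_wav <- function(path, participant_id = NA_character_, site_id = NA_character_,
                     label = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  sample_rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV supported: ", path)
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (identical(id, "data")) {
      nsmp <- sz %/% 2L
      samples <- readBin(con, "integer", nsmp, size = 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      readBin(con, "raw", sz)  # skip unknown chunk
    }
  }
  if (is.null(sample_rate) || is.null(samples)) stop("malformed WAV: ", path)
  if (channels != 1L) stop("only mono WAV supported (", channels, " channels): ", path)
  if (bits != 16L) stop("only 16-bit PCM supported (", bits, " bits): ", path)
  new_recording(samples / 32767, sample_rate,
                participant_id = participant_id, site_id = site_id, label = label)
}

new_recording <- function(samples, sample_rate, participant_id = NA_character_,
                          site_id = NA_character_, label = NA_integer_) {
  stopifnot(sample_rate > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate),
                 participant_id = participant_id, site_id = site_id,
                 label = label),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s / %s  label=%s  %.2f s @ %d Hz\n",
              x$participant_id, x$site_id, x$label,
              length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}
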