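#' Audio clip container
#'
#' A minimal container for mono audio: a numeric sample vector in
#' \[-1, 1\] plus a sampling rate in Hz.
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param rate Sampling rate in samples per second.
#' @return An object of class `audio_clip` with fields `samples` and `rate`.
#' @export
audio_clip <- function(samples, rate) {
  check_positive(rate, "rate")
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("'samples' must be finite", call. = FALSE)
  }
  if (max(abs(samples)) > 1 + 1e-9) {
    stop("'samples' must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %.3f s at %g Hz>\n",
              length(x$samples) / x$rate, x$rate))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$rate

#' Write a clip as 16-bit PCM mono WAV
#'
#' Writes the canonical 44-byte RIFF/WAVE header followed by little-endian
#' 16-bit signed samples.
#'
#' @param clip An `audio_clip`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  pcm <- as.integer(round(pmax(-1, pmin(1, clip$samples)) * 32767))
  n <- length(pcm)
  rate <- as.integer(round(clip$rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path Path to a WAV file written by [write_wav()] (PCM, mono,
#'   16-bit; no extension chunks before `data` are skipped other than by
#'   scanning for the `data` tag).
#' @return An `audio_clip`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file", call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file", call. = FALSE)
  rate <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) stop("no data chunk", call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("only 16-bit PCM mono WAV is supported", call. = FALSE)
      }
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", size - 8L))
    } else if (identical(tag, "data")) {
      if (is.null(rate)) stop("data chunk before fmt chunk", call. = FALSE)
      pcm <- readBin(con, "integer", size %/% 2L, size = 2, signed = TRUE,
                     endian = "little")
      return(audio_clip(pcm / 32767, rate))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}
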