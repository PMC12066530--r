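#' Construct an audio signal object
#'
#' An `audio_signal` is the basic container passed between all pipeline
#' stages: a mono amplitude sequence in \[-1, 1\] with its sampling rate.
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param rate Sampling rate in Hz (> 0).
#' @param id Recording identifier string.
#' @return An object of class `audio_signal` with fields `samples`, `rate`,
#'   `id`.
#' @export
audio_signal <- function(samples, rate, id = "signal") {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    rlang::abort("`rate` must be a single positive number.", class = "prosodia_argument_error")
  }
  if (length(samples) < 1L) {
    rlang::abort("`samples` must have length >= 1.", class = "prosodia_argument_error")
  }
  samples <- as.numeric(samples)
  peak <- max(abs(samples))
  if (is.finite(peak) && peak > 1) samples <- samples / peak
  structure(
    list(samples = samples, rate = as.numeric(rate), id = as.character(id)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal '%s': %.3f s @ %g Hz (%d samples)>\n",
    x$id, length(x$samples) / x$rate, x$rate, length(x$samples)
  ))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param sig An `audio_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(sig) length(sig$samples) / sig$rate

# Minimal RIFF/WAVE chunk walker. Returns list(fmt = ..., data_raw = raw()).
.wav_parse <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    rlang::abort(sprintf("Not a RIFF/WAVE file: %s", path), class = "prosodia_format_error")
  }
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    rlang::abort(sprintf("Not a RIFF/WAVE file: %s", path), class = "prosodia_format_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format   = sum(as.integer(body[1:2]) * c(1L, 256L)),
        channels = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate     = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits     = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
      # WAVE_FORMAT_EXTENSIBLE: true format is in the sub-format GUID
      if (fmt$format == 65534L && size >= 26L) {
        fmt$format <- sum(as.integer(body[25:26]) * c(1L, 256L))
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L)) # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    rlang::abort(sprintf("Missing fmt/data chunk in WAV file: %s", path),
      class = "prosodia_format_error"
    )
  }
  list(fmt = fmt, data_raw = data_raw)
}

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE PCM audio (16- or 24-bit integer, or 32-bit float).
#' Multichannel input is mixed down to mono by the arithmetic channel mean;
#' integer samples are scaled to \[-1, 1\]. The sampling rate is preserved
#' (no resampling: all downstream stages operate at the native rate).
#'
#' @param path Path to a WAV file.
#' @param id Recording identifier; defaults to the file name without
#'   extension.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path, id = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File does not exist: %s", path), class = "prosodia_format_error")
  }
  parsed <- .wav_parse(path)
  fmt <- parsed$fmt
  raw <- parsed$data_raw
  x <- switch(as.character(fmt$format),
    "1" = { # integer PCM
      if (fmt$bits == 16L) {
        readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
          signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        n <- length(raw) %/% 3L
        b <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
        v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (fmt$bits == 8L) {
        (as.integer(raw) - 128) / 128
      } else {
        rlang::abort(sprintf("Unsupported PCM bit depth %d in %s", fmt$bits, path),
          class = "prosodia_format_error"
        )
      }
    },
    "3" = readBin(raw, "numeric", n = length(raw) %/% 4L, size = 4L, endian = "little"),
    rlang::abort(sprintf("Unsupported WAV encoding (format tag %d) in %s", fmt$format, path),
      class = "prosodia_format_error"
    )
  )
  if (fmt$channels > 1L) {
    nfr <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(nfr * fmt$channels)], nrow = fmt$channels))
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  audio_signal(x, fmt$rate, id = id)
}

#' Write an audio signal to a 16-bit PCM WAV file
#'
#' @param sig An [audio_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(sig, path) {
  x <- pmax(pmin(sig$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")  # PCM
  writeBin(1L, con, size = 2L, endian = "little")  # mono
  writeBin(as.integer(sig$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sig$rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")  # block align
  writeBin(16L, con, size = 2L, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Slice a signal into overlapping frames with center times
#'
#' Frame `k` (0-based) is centered at `k * hop_s`; edges are zero-padded so
#' every sample belongs to at least one frame. The number of frames is
#' `floor(duration / hop_s) + 1`.
#'
#' @param sig An [audio_signal()].
#' @param win_s Window length in seconds.
#' @param hop_s Hop (frame step) in seconds; `0 < hop_s <= win_s`.
#' @return List with `frames` (matrix, one column per frame), `centers_s`
#'   (numeric vector of frame center times), `win_n` (samples per frame).
#' @export
frame_signal <- function(sig, win_s, hop_s) {
  if (!is.numeric(win_s) || !is.numeric(hop_s) || win_s <= 0 || hop_s <= 0 || hop_s > win_s) {
    rlang::abort("Need 0 < hop_s <= win_s.", class = "prosodia_argument_error")
  }
  win_n <- max(2L, as.integer(round(win_s * sig$rate)))
  n <- length(sig$samples)
  dur <- n / sig$rate
  n_frames <- as.integer(floor(dur / hop_s + 1e-9)) + 1L
  centers_s <- (seq_len(n_frames) - 1L) * hop_s
  half <- win_n %/% 2L
  padded <- c(numeric(half), sig$samples, numeric(win_n))
  starts <- as.integer(round(centers_s * sig$rate)) # 0-based offsets into padded
  idx <- outer(seq_len(win_n), starts, `+`)
  frames <- matrix(padded[idx], nrow = win_n)
  list(frames = frames, centers_s = centers_s, win_n = win_n)
}
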