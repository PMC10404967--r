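#' Construct an audio signal
#'
#' A light container for a sampled sound: numeric samples, the sampling
#' rate in Hz and a free-text source identifier.
#'
#' @param samples Numeric vector of amplitudes (length >= 1, all finite).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param source_id Character tag naming where the signal came from.
#' @return An object of class `audio_signal` with fields `samples`,
#'   `sample_rate` and `source_id`.
#' @export
audio_signal <- function(samples, sample_rate, source_id = "unknown") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio signal must contain at least one sample")
  assert_finite(samples, "audio samples")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         source_id = as.character(source_id)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %s: %d samples @ %g Hz (%.3f s)\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param signal An `audio_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(signal) length(signal$samples) / signal$sample_rate

#' Min-max normalization of a signal to \[0, 1\]
#'
#' Order-preserving affine map `(x - min) / (max - min)`. The minimum of
#' the output is exactly 0 and the maximum exactly 1. Constant signals
#' have a zero denominator and are rejected.
#'
#' @param signal An `audio_signal` or a bare numeric vector.
#' @return Object of the same kind as the input, samples in \[0, 1\].
#' @export
normalize_minmax <- function(signal) {
  x <- if (inherits(signal, "audio_signal")) signal$samples else as.numeric(signal)
  assert_finite(x, "signal")
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("cannot min-max normalize a constant signal (zero denominator)")
  y <- (x - rng[1]) / (rng[2] - rng[1])
  if (inherits(signal, "audio_signal")) {
    signal$samples <- y
    signal
  } else y
}

#' Resample a signal to a new rate
#'
#' Linear-interpolation resampling, preceded by a crude FFT low-pass at
#' the new Nyquist frequency when downsampling (anti-aliasing).
#'
#' @param signal An `audio_signal`.
#' @param new_rate Target sampling rate in Hz.
#' @return A resampled `audio_signal`.
#' @export
resample_signal <- function(signal, new_rate) {
  stopifnot(inherits(signal, "audio_signal"), new_rate > 0)
  if (new_rate == signal$sample_rate) return(signal)
  x <- signal$samples
  if (new_rate < signal$sample_rate)
    x <- fft_bandpass(x, signal$sample_rate, 0, new_rate / 2)
  n_new <- max(1L, round(length(x) * new_rate / signal$sample_rate))
  t_old <- (seq_along(x) - 1) / signal$sample_rate
  t_new <- (seq_len(n_new) - 1) / new_rate
  y <- stats::approx(t_old, x, xout = pmin(t_new, max(t_old)), rule = 2)$y
  audio_signal(y, new_rate, signal$source_id)
}

# Brick-wall FFT band-pass filter, [lo, hi] in Hz. Used for synthesis and
# anti-aliasing; sharp edges are acceptable for broadband noise shaping.
#' @keywords internal
#' @noRd
fft_bandpass <- function(x, sample_rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * sample_rate / n
  freqs <- pmin(freqs, sample_rate - freqs)   # fold to [0, fs/2]
  X[freqs < lo | freqs > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader covering 16-bit integer and 32-bit IEEE
#' float mono PCM, the formats used by the lung-sound databases this
#' package targets. Samples are rescaled to \[-1, 1\] for integer PCM.
#'
#' @param path Path to a `.wav` file.
#' @return An `audio_signal`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop(sprintf("WAV file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- sz - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$channels != 1L) stop("only mono WAV supported, got ", fmt$channels, " channels")
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) %/% 4L, 4L, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bits)", fmt$audio_format, fmt$bits))
  }
  audio_signal(x, fmt$sample_rate, source_id = basename(path))
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param signal An `audio_signal`; samples are clipped to \[-1, 1\].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- pmax(-1, pmin(1, signal$samples))
  pcm <- as.integer(pmin(32767, round(x * 32768)))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                       # PCM
  writeBin(1L, con, 2L, endian = "little")                       # mono
  writeBin(as.integer(signal$sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(signal$sample_rate * 2L), con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}
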