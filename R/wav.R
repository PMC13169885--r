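#' Write a waveform to a PCM WAV file
#'
#' Writes mono 16-bit little-endian PCM. Samples are full-scale amplitudes in
#' \[-1, 1\]; values outside that range are clipped.
#'
#' @param samples Numeric vector of samples in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  if (any(!is.finite(samples))) stop("input error: non-finite samples")
  x <- pmin(pmax(samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Supports 16- and 24-bit integer PCM; stereo is downmixed by channel
#' averaging. Returns a waveform in full-scale units.
#'
#' @param path WAV file path.
#' @return A list with `samples` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("input error: not a RIFF/WAVE file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    stop("input error: not a RIFF/WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, raw(), n = sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(raw[3:4]) * c(1L, 256L)),
        sample_rate  = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits         = sum(as.integer(raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), n = sz)
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("input error: malformed WAV: ", path)
  if (fmt$audio_format != 1L) stop("input error: only integer PCM WAV supported")
  if (!fmt$bits %in% c(16L, 24L)) stop("input error: only 16/24-bit PCM supported")
  if (fmt$bits == 16L) {
    v <- readBin(data_raw, integer(), n = length(data_raw) %/% 2L,
                 size = 2, signed = TRUE, endian = "little")
    x <- v / 32768
  } else {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
    v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  }
  if (fmt$n_channels > 1L) {
    nc <- fmt$n_channels
    nf <- length(x) %/% nc
    x <- rowMeans(matrix(x[seq_len(nf * nc)], ncol = nc, byrow = TRUE))
  }
  list(samples = x, sample_rate = fmt$sample_rate)
}
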