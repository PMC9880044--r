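#' Read a single-channel WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats this package writes and the
#' common field recordings it consumes: PCM 16-bit, PCM 24-bit, PCM 32-bit and
#' IEEE float32/float64, mono. Samples are returned as doubles scaled to
#' [-1, 1] (PCM) or as stored (float).
#'
#' @param path path to a .wav file.
#' @return list with elements `wave` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw_fmt[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(raw_fmt[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(raw_fmt[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw_fmt[15:16]) * c(1, 256))
      )
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$n_channels != 1L)
        stop("multi-channel WAV not supported; mix down to mono first (",
             fmt$n_channels, " channels in ", path, ")")
      bytes_per <- fmt$bits %/% 8L
      n <- sz %/% bytes_per
      wave <- if (fmt$audio_format == 3L) {  # IEEE float
        readBin(con, "double", n, size = bytes_per, endian = "little")
      } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
        readBin(con, "integer", n, size = 2, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
        raw3 <- readBin(con, "raw", sz)
        b <- matrix(as.integer(raw3), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
        readBin(con, "integer", n, size = 4, endian = "little") / 2147483648
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format,
             ", ", fmt$bits, " bit)")
      }
      return(list(wave = wave, sample_rate = fmt$sample_rate))
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
  }
}

#' Write a single-channel WAV file
#'
#' @param wave numeric samples in [-1, 1].
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @param format `"float32"` (default, lossless for synthetic scenes) or
#'   `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, sample_rate, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(wave)
  bytes_per <- if (format == "float32") 4L else 2L
  data_sz <- n * bytes_per
  fmt_tag <- if (format == "float32") 3L else 1L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")         # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")    # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(wave), con, size = 4, endian = "little")
  } else {
    v <- as.integer(round(pmax(pmin(wave, 1), -1) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  }
  invisible(path)
}
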