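# Minimal mono WAV I/O (PCM 16-bit and IEEE float32). Only the subset of the
# RIFF format needed for motif stimuli is supported.

#' Write a mono WAV file
#'
#' @param samples numeric vector in \[-1, 1\] (clipped if outside).
#' @param rate_hz sampling rate in Hz.
#' @param path output file path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate_hz, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(is.numeric(samples), length(samples) >= 1, rate_hz > 0)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  if (format == "pcm16") {
    bytes_per <- 2L; audio_fmt <- 1L; bits <- 16L
    data_size <- n * bytes_per
  } else {
    bytes_per <- 4L; audio_fmt <- 3L; bits <- 32L
    data_size <- n * bytes_per
  }
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rate_hz * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- pmax(-1, pmin(1, samples))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' @param path input file path.
#' @return list with `samples` (numeric, PCM rescaled to \[-1, 1\]) and
#'   `rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop2("not a RIFF/WAV file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop2("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop2("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", n = size)
      fmt <- list(
        audio_fmt = readBin(raw_fmt[1:2], integer(), size = 2, endian = "little"),
        channels  = readBin(raw_fmt[3:4], integer(), size = 2, endian = "little"),
        rate_hz   = readBin(raw_fmt[5:8], integer(), size = 4, endian = "little"),
        bits      = readBin(raw_fmt[15:16], integer(), size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop2("data chunk before fmt chunk in ", path)
      if (fmt$channels != 1L) stop2("only mono WAV supported: ", path)
      if (fmt$audio_fmt == 1L && fmt$bits == 16L) {
        x <- readBin(con, integer(), n = size / 2, size = 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt$audio_fmt == 3L && fmt$bits == 32L) {
        x <- readBin(con, numeric(), n = size / 4, size = 4, endian = "little")
      } else {
        stop2("unsupported WAV encoding (fmt ", fmt$audio_fmt, ", ",
              fmt$bits, " bit): ", path)
      }
      return(list(samples = as.numeric(x), rate_hz = fmt$rate_hz))
    } else {
      invisible(readBin(con, "raw", n = size + size %% 2))
    }
  }
}
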