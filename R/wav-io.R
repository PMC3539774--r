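#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the encodings the toolchain writes: 16-bit
#' integer PCM (format tag 1) and 32- or 64-bit IEEE float (format tag 3).
#' PCM samples are normalized to `[-1, 1)` by dividing by 32768; float
#' samples are returned as stored, so a 64-bit float write/read round trip
#' is bit-exact. Stereo or multi-channel files are an error, never a
#' silent downmix.
#'
#' @param path Path to a WAV file.
#' @return List with `wave` (numeric samples) and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        sample_rate = readBin(body[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(body[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path)
  if (fmt$channels != 1L) {
    stop("expected mono audio, file has ", fmt$channels,
         " channels (no silent downmix)")
  }
  samples <- if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2,
            endian = "little", signed = TRUE) / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4,
            endian = "little")
  } else if (fmt$audio_format == 3L && fmt$bits == 64L) {
    readBin(data_raw, "double", length(data_raw) %/% 8L, size = 8,
            endian = "little")
  } else {
    stop("unsupported WAV encoding: format tag ", fmt$audio_format, ", ",
         fmt$bits, " bits")
  }
  list(wave = samples, sample_rate_hz = fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param path Output path.
#' @param wave Numeric samples in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param format `"float"` (64-bit IEEE, bit-exact round trip; default),
#'   `"float32"` (32-bit IEEE), or `"pcm16"` (16-bit integer, quantization
#'   error at most 1/32768).
#' @return `path`, invisibly.
#' @export
write_wav <- function(path, wave, sample_rate_hz,
                      format = c("float", "float32", "pcm16")) {
  format <- match.arg(format)
  wave <- as.numeric(wave)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(wave)
  if (format == "float") {
    bits <- 64L; tag <- 3L; bytes <- 8L
  } else if (format == "float32") {
    bits <- 32L; tag <- 3L; bytes <- 4L
  } else {
    bits <- 16L; tag <- 1L; bytes <- 2L
  }
  data_size <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * bytes), con, size = 4,
           endian = "little")                                  # byte rate
  writeBin(as.integer(bytes), con, size = 2, endian = "little")  # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float") {
    writeBin(wave, con, size = 8, endian = "little")
  } else if (format == "float32") {
    writeBin(wave, con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(wave * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}
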