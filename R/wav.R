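# Minimal RIFF/WAVE reader and writer covering the subset the pipeline
# produces and consumes: mono PCM 16-bit or IEEE float32. Samples are held
# as doubles in [-1, 1].

#' Read a mono WAV file
#'
#' Supports PCM 16-bit (format 1) and IEEE float32 (format 3) mono files.
#'
#' @param path file path.
#' @return list with `samples` (double, PCM scaled to `[-1, 1)`) and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(raw_fmt[1:2], "integer", 1, size = 2, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, size = 2, endian = "little"),
        rate = readBin(raw_fmt[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: missing fmt/data chunk")
  if (fmt$channels != 1L) stop("only mono WAV supported, got ", fmt$channels, " channels")
  if (fmt$format == 1L && fmt$bits == 16L) {
    samples <- pmax(readBin(data, "integer", n = length(data) / 2, size = 2,
                            signed = TRUE, endian = "little") / 32767, -1)
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    samples <- readBin(data, "double", n = length(data) / 4, size = 4,
                       endian = "little")
  } else {
    stop("unsupported WAV encoding: format ", fmt$format, ", ", fmt$bits, " bits")
  }
  list(samples = samples, rate = fmt$rate)
}

#' Write a mono PCM 16-bit WAV file
#'
#' @param samples numeric vector in `[-1, 1]` (clipped if outside).
#' @param rate sample rate in Hz.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
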