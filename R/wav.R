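## Minimal RIFF/WAVE i/o for mono stimuli. Supports PCM 16/24-bit and IEEE
## float 32; everything the stimulus generators emit and the coder consumes.

#' Read a mono WAV file
#'
#' @param path file path.
#' @return list with `samples` (numeric in [-1, 1]) and `sample_rate` (Hz).
#'   Multi-channel files are averaged down to mono.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        format    = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels  = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate      = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  x <- switch(as.character(fmt$format),
    "1" = {
      if (fmt$bits == 16) {
        readBin(data_raw, "integer", length(data_raw) / 2, 2,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24) {
        n <- length(data_raw) / 3
        b <- matrix(as.integer(data_raw), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little"),
    stop("unsupported WAV format code: ", fmt$format))
  if (fmt$channels > 1) {
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  }
  list(samples = as.numeric(x), sample_rate = fmt$rate)
}

#' Write a mono WAV file
#'
#' @param samples numeric waveform in [-1, 1].
#' @param sample_rate sampling rate, Hz.
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16) {
  stopifnot(bits %in% c(16, 32))
  n <- length(samples)
  bytes_per <- bits / 8
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  fmt_code <- if (bits == 16) 1L else 3L
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (bits == 16) {
    v <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
    writeBin(v, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}
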