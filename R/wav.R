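## Minimal RIFF/WAVE PCM I/O. Supports 16- and 24-bit integer PCM; stereo
## files are reduced to the left channel. Samples are returned as doubles in
## [-1, 1].

#' Read a PCM WAV file
#'
#' @param path file path.
#' @return list with \code{samples} (numeric vector in [-1, 1], left channel
#'   only for multichannel files) and \code{rate} (Hz).
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", sz)
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt/data chunk: ", path)
  le16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1])
  le32 <- function(r, i) le16(r, i) + 65536 * le16(r, i + 2)
  audioFormat <- le16(fmt, 1); nCh <- le16(fmt, 3)
  rate <- le32(fmt, 5); bits <- le16(fmt, 15)
  if (audioFormat != 1L) stop("only integer PCM WAV supported")
  if (!bits %in% c(16L, 24L)) stop("only 16/24-bit PCM supported, got ", bits)
  bytes <- bits %/% 8L
  n <- length(data) %/% (bytes * nCh)
  raw <- data[seq_len(n * bytes * nCh)]
  m <- matrix(as.integer(raw), nrow = bytes * nCh)
  left <- m[seq_len(bytes), , drop = FALSE]
  if (bytes == 2L) {
    v <- left[1, ] + 256L * left[2, ]
    v <- ifelse(v >= 32768L, v - 65536L, v)
    samples <- v / 32767
  } else {
    v <- left[1, ] + 256 * left[2, ] + 65536 * left[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    samples <- v / 8388607
  }
  list(samples = as.numeric(samples), rate = rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in [-1, 1]; values outside are clipped.
#' @param rate sample rate, Hz.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(samples, rate, path) {
  v <- round(pmin(pmax(samples, -1), 1) * 32767)
  v <- as.integer(v)
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(v)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")          # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(v, con, 2, endian = "little")
  invisible(path)
}
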