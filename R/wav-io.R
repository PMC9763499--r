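# Minimal RIFF/WAVE reader and writer for PCM (8/16/24-bit integer) and
# IEEE-float (32-bit) files. Chunk-walks the RIFF container so extra chunks
# (LIST, bext, ...) are skipped rather than fatal.

#' Read a PCM WAV file
#'
#' Supports uncompressed 8/16/24-bit integer PCM and 32-bit IEEE float,
#' mono or multi-channel. Samples are rescaled to \eqn{[-1, 1]}.
#'
#' @param path path to a .wav file.
#' @return a [Waveform-class]; multi-channel audio comes back as a
#'   samples-by-channels matrix.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = readBin(raw[1:2], "integer", 1, 2, signed = FALSE,
                              endian = "little"),
        nChannels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE,
                            endian = "little"),
        sampleRate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bitsPerSample = readBin(raw[15:16], "integer", 1, 2, signed = FALSE,
                                endian = "little"))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt/data chunk: ", path)
  bits <- fmt$bitsPerSample
  x <- if (fmt$audioFormat == 3L && bits == 32L) {
    readBin(data, "numeric", length(data) / 4, 4, endian = "little")
  } else if (fmt$audioFormat == 1L && bits == 16L) {
    readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$audioFormat == 1L && bits == 8L) {
    (readBin(data, "integer", length(data), 1, signed = FALSE) - 128) / 128
  } else if (fmt$audioFormat == 1L && bits == 24L) {
    n <- length(data) / 3
    b <- matrix(as.integer(data), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                 fmt$audioFormat, bits))
  }
  if (fmt$nChannels > 1L)
    x <- matrix(x, ncol = fmt$nChannels, byrow = TRUE)
  waveform(x, fmt$sampleRate)
}

#' Write a PCM WAV file
#'
#' @param w a [Waveform-class]; values outside \eqn{[-1, 1]} are clipped.
#' @param path output path.
#' @param bitDepth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
writeWav <- function(w, path, bitDepth = 16L) {
  s <- w@samples
  if (!is.matrix(s)) s <- matrix(s, ncol = 1L)
  nch <- ncol(s)
  inter <- as.vector(t(s))  # interleave channels
  inter <- pmin(1, pmax(-1, inter))
  con <- file(path, "wb")
  on.exit(close(con))
  if (bitDepth == 16L) {
    pcm <- as.integer(pmin(32767, round(inter * 32768)))
    bytesPerSample <- 2L
    fmtCode <- 1L
  } else if (bitDepth == 32L) {
    bytesPerSample <- 4L
    fmtCode <- 3L
  } else stop("bitDepth must be 16 or 32")
  dataSize <- length(inter) * bytesPerSample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmtCode, con, 2, endian = "little")
  writeBin(nch, con, 2, endian = "little")
  writeBin(as.integer(w@sampleRate), con, 4, endian = "little")
  writeBin(as.integer(w@sampleRate * nch * bytesPerSample), con, 4,
           endian = "little")
  writeBin(as.integer(nch * bytesPerSample), con, 2, endian = "little")
  writeBin(as.integer(bitDepth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4, endian = "little")
  if (bitDepth == 16L) {
    writeBin(pcm, con, 2, endian = "little")
  } else {
    writeBin(inter, con, 4, endian = "little")
  }
  invisible(path)
}
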