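# Minimal RIFF/WAVE reader and writer for mono 16-bit PCM, the format used
# by the ultrasound recorders this package targets (192-200 kHz sampling).

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\]; values outside the
#'   range are clipped.
#' @param sample_rate sampling frequency in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  x <- pmax(-1, pmin(1, samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file path.
#' @return A list with `samples` (numeric in \[-1, 1\]) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  sample_rate <- NULL
  channels <- bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      channels <- fmt[2]
      if (fmt[1] != 1L) stop("only PCM WAV supported: ", path)
      if (size > 16) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      if (is.null(sample_rate)) stop("data chunk before fmt chunk in ", path)
      if (channels != 1L || bits != 16L) {
        stop("only mono 16-bit WAV supported: ", path)
      }
      pcm <- readBin(con, "integer", n = size / 2, size = 2,
                     signed = TRUE, endian = "little")
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
  }
}
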