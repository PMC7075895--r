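# Minimal RIFF/WAVE PCM 16-bit mono I/O.
#
# The pipeline's interchange format for audio is single-channel 16-bit PCM
# WAV; these readers/writers cover exactly that profile and reject anything
# else with a clear message.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param wave numeric vector in \[-1, 1\] (values are clipped).
#' @param sample_rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, sample_rate, path) {
  stopifnot(is.numeric(wave), length(wave) > 0, sample_rate > 0)
  pcm <- as.integer(round(pmin(pmax(wave, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @return list with `wave` (numeric in \[-1, 1\]) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave_tag <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave_tag, "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4)
      stop("corrupt WAV (no data chunk): ", path, call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
      if (fmt[1] != 1L) stop("unsupported WAV encoding (not PCM): ", path,
                             call. = FALSE)
    } else if (identical(id, "data")) {
      if (is.null(sample_rate)) stop("corrupt WAV (data before fmt): ", path,
                                     call. = FALSE)
      if (bits != 16L || channels != 1L)
        stop("only 16-bit mono PCM supported: ", path, call. = FALSE)
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      return(list(wave = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
}
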