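#' Write a mono waveform to a WAV file
#'
#' Writes a standard RIFF/WAVE file, either 16-bit integer PCM (format 1) or
#' 32-bit IEEE float (format 3). Samples outside \[-1, 1\] are clipped for the
#' 16-bit format.
#'
#' @param w a `waveform` (list with `samples`, `sampling_rate_hz`).
#' @param path output file path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16) {
  if (!bits %in% c(16, 32)) stop_volecall("bits must be 16 or 32")
  x <- w$samples
  rate <- as.integer(w$sampling_rate_hz)
  n <- length(x)
  bytes_per_sample <- bits / 8
  data_size <- n * bytes_per_sample
  fmt_code <- if (bits == 16) 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per_sample), con, size = 4,
           endian = "little")                               # byte rate
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Reads RIFF/WAVE files containing mono 16-bit PCM or 32-bit IEEE float
#' audio, skipping unknown chunks.
#'
#' @param path WAV file path.
#' @return a `waveform` (samples scaled to \[-1, 1\] for PCM input).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_volecall("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop_volecall("not a WAVE file: ", path)
  fmt_code <- NULL; rate <- NULL; bits <- NULL; channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4)
      stop_volecall("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt_code)) stop_volecall("data chunk precedes fmt chunk")
      if (channels != 1L) stop_volecall("only mono WAV is supported")
      if (fmt_code == 1L && bits == 16L) {
        x <- readBin(con, integer(), n = size / 2, size = 2,
                     endian = "little", signed = TRUE) / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        x <- readBin(con, numeric(), n = size / 4, size = 4,
                     endian = "little")
      } else {
        stop_volecall("unsupported WAV encoding (format ", fmt_code, ", ",
                      bits, " bit)")
      }
      return(structure(list(samples = x, sampling_rate_hz = rate),
                       class = "waveform"))
    } else {
      readBin(con, raw(), n = size + (size %% 2))  # skip, chunks are padded
    }
  }
}
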