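# Persistence: mono 32-bit-float WAV for waveforms, two-column CSV for
# impulse responses, RDS for fitted encoding bases.

#' Write a waveform to a WAV file
#'
#' Mono, IEEE float32, sample rate from the waveform.
#'
#' @param echo An `echo_wave`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(echo, path) {
  if (!inherits(echo, "echo_wave")) stop("`echo` must be an echo_wave")
  n <- length(echo$samples)
  data_bytes <- n * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")          # IEEE float
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(echo$fs), con, size = 4, endian = "little")
  writeBin(as.integer(echo$fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")          # block align
  writeBin(32L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(echo$samples, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono float32 WAV file
#'
#' @param path File path.
#' @return An `echo_wave`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAV file")
  fs <- NULL; fmt <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      ch <- readBin(con, integer(), size = 2, endian = "little")
      if (ch != 1L) stop("only mono WAV files are supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16L) invisible(readBin(con, raw(), n = sz - 16L))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk")
      if (fmt != 3L || bits != 32L)
        stop("only IEEE float32 WAV files are supported")
      x <- readBin(con, numeric(), n = sz / 4L, size = 4, endian = "little")
      return(echo_wave(x, fs = fs))
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2L))
    }
  }
}

#' Write an impulse response as CSV
#'
#' Two columns: `delay_s`, `amplitude`.
#'
#' @param ir An `impulse_response`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ir_csv <- function(ir, path) {
  if (!inherits(ir, "impulse_response")) stop("`ir` must be an impulse_response")
  utils::write.csv(data.frame(delay_s = ir$delays, amplitude = ir$amplitudes),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an impulse response from CSV
#'
#' @param path File path (columns `delay_s`, `amplitude`).
#' @param allow_negative Permit negative amplitudes.
#' @return An `impulse_response`.
#' @export
read_ir_csv <- function(path, allow_negative = FALSE) {
  d <- utils::read.csv(path)
  impulse_response(d$delay_s, d$amplitude, allow_negative = allow_negative)
}

#' Persist / restore a fitted encoding basis
#'
#' Stored as a single RDS file holding the basis object (mean, PCA
#' components, variance ratios, ICA rotation, fit metadata).
#'
#' @param basis An `encoding_basis`.
#' @param path File path.
#' @return `path` (write) or the `encoding_basis` (read).
#' @export
write_basis <- function(basis, path) {
  if (!inherits(basis, "encoding_basis")) stop("`basis` must be an encoding_basis")
  saveRDS(basis, path)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "encoding_basis")) stop("file does not hold an encoding_basis")
  b
}
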