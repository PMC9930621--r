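#' Write a waveform to a RIFF WAV file
#'
#' Minimal writer for mono 16-bit PCM or 32-bit IEEE-float WAV. Provided
#' because the analysis exchanges stimuli as WAV; only the subset of the
#' format the package itself produces is supported.
#'
#' @param x A `sound_token` or numeric vector in `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Required when `x` is a bare vector.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = NULL, bits = 16) {
  if (inherits(x, "sound_token")) {
    sample_rate <- x$sample_rate; x <- x$samples
  }
  stopifnot(!is.null(sample_rate), bits %in% c(16, 32))
  n <- length(x)
  bytes_per <- bits / 8
  data_len <- n * bytes_per
  fmt <- if (bits == 16) 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a RIFF WAV file written by [write_wav()]
#'
#' @param path File path.
#' @return List with `samples` and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  fmt_code <- NULL; sample_rate <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (len > 16) invisible(readBin(con, "raw", n = len - 16))
    } else if (id == "data") {
      if (bits == 16) {
        samples <- readBin(con, "integer", n = len / 2, size = 2,
                           endian = "little") / 32767
      } else {
        samples <- readBin(con, "numeric", n = len / 4, size = 4,
                           endian = "little")
      }
      break
    } else {
      invisible(readBin(con, "raw", n = len))
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  list(samples = samples, sample_rate = sample_rate)
}
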