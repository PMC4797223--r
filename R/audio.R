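#' Audio buffer
#'
#' In-memory audio container used by all processors. Samples are held as a
#' numeric matrix with one column per channel; processing is always done in
#' floating point regardless of the on-disk encoding.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param rate Sample rate in Hz. Filters centered up to 12 kHz need
#'   `rate >= 32000` to keep a Nyquist margin above the upper edge band.
#' @return An object of class `audio_buffer`.
#' @examples
#' b <- audio_buffer(sin(2 * pi * 440 * seq(0, 1, by = 1 / 48000)), 48000)
#' n_samples(b)
#' @export
audio_buffer <- function(samples, rate) {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric vector or matrix (one column per channel)")
  }
  if (!ncol(samples) %in% c(1L, 2L)) {
    stop("only mono or stereo buffers are supported (1 or 2 columns)")
  }
  rate <- as.numeric(rate)
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number")
  }
  structure(list(samples = samples, rate = rate), class = "audio_buffer")
}

#' @rdname audio_buffer
#' @param x An `audio_buffer`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname audio_buffer
#' @export
n_channels <- function(x) ncol(x$samples)

#' @rdname audio_buffer
#' @export
duration_s <- function(x) nrow(x$samples) / x$rate

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf(
    "<audio_buffer> %d channel(s), %d samples @ %g Hz (%.2f s), peak %.3f\n",
    n_channels(x), n_samples(x), x$rate, duration_s(x),
    max(abs(x$samples))
  ))
  invisible(x)
}

#' Root-mean-square level of a buffer
#' @param x An `audio_buffer`.
#' @return RMS over all channels (linear amplitude).
#' @export
rms <- function(x) sqrt(mean(x$samples^2))

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All seeded operations in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Read a WAV file
#'
#' Reads RIFF/WAVE files encoded as PCM 16-bit, PCM 24-bit or IEEE float32
#' into an [audio_buffer()]. Samples are returned in floating point on the
#' \[-1, 1\] scale.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_buffer()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little") # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("truncated WAV file: ", path)
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(size) == 0L) stop("truncated WAV file: ", path)
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      if (length(raw_fmt) < 16L) stop("truncated fmt chunk: ", path)
      u16 <- function(i) sum(as.integer(raw_fmt[i:(i + 1L)]) * c(1, 256))
      u32 <- function(i) sum(as.numeric(raw_fmt[i:(i + 3L)]) * 256^(0:3))
      fmt <- list(
        format = u16(1L), channels = u16(3L), rate = u32(5L),
        bits = u16(15L)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("WAV data chunk precedes fmt chunk: ", path)
      bytes_per <- fmt$bits %/% 8L
      n_vals <- size %/% bytes_per
      if (fmt$format == 3L && fmt$bits == 32L) {
        vals <- readBin(con, "numeric", n_vals, size = 4L, endian = "little")
      } else if (fmt$format == 1L && fmt$bits == 16L) {
        vals <- readBin(con, "integer", n_vals, size = 2L,
                        signed = TRUE, endian = "little") / 32768
      } else if (fmt$format == 1L && fmt$bits == 24L) {
        raw <- readBin(con, "raw", n_vals * 3L)
        if (length(raw) < n_vals * 3L) stop("truncated WAV data: ", path)
        m <- matrix(as.numeric(raw), nrow = 3L)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        vals <- ifelse(v >= 2^23, v - 2^24, v) / 2^23
      } else {
        stop(sprintf(
          "unsupported WAV encoding (format tag %d, %d bit); supported: PCM16, PCM24, float32",
          fmt$format, fmt$bits
        ))
      }
      if (length(vals) < n_vals) stop("truncated WAV data: ", path)
      return(audio_buffer(
        matrix(vals, ncol = fmt$channels, byrow = TRUE), fmt$rate
      ))
    } else {
      seek(con, size + size %% 2L, origin = "current")
    }
  }
}

#' Write a WAV file
#'
#' Writes an [audio_buffer()] as RIFF/WAVE. float32 round-trips losslessly;
#' PCM is quantized with clipping detection (a warning is raised if any
#' sample exceeds full scale).
#'
#' @param x An [audio_buffer()].
#' @param path Output path.
#' @param bit_depth One of `"float32"` (default), `"pcm16"`, `"pcm24"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bit_depth = c("float32", "pcm16", "pcm24")) {
  bit_depth <- match.arg(bit_depth)
  stopifnot(inherits(x, "audio_buffer"))
  if (max(abs(x$samples)) > 1 && bit_depth != "float32") {
    warning("samples exceed full scale; PCM output will clip")
  }
  interleaved <- as.numeric(t(x$samples))
  ch <- n_channels(x)
  bits <- switch(bit_depth, float32 = 32L, pcm16 = 16L, pcm24 = 24L)
  tag <- if (bit_depth == "float32") 3L else 1L
  bytes_per <- bits %/% 8L
  data_size <- length(interleaved) * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(tag, con, size = 2L, endian = "little")
  writeBin(ch, con, size = 2L, endian = "little")
  writeBin(as.integer(x$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(x$rate * ch * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(ch * bytes_per), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bit_depth == "float32") {
    writeBin(interleaved, con, size = 4L, endian = "little")
  } else if (bit_depth == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(interleaved * 32768))))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    q <- round(pmax(-2^23, pmin(2^23 - 1, interleaved * 2^23)))
    q <- ifelse(q < 0, q + 2^24, q)
    raw <- as.raw(rbind(q %% 256, (q %/% 256) %% 256, q %/% 65536))
    writeBin(as.vector(raw), con)
  }
  invisible(path)
}
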