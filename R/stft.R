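# Short-time spectral engine: Hann-windowed STFT with 75 % overlap and
# weighted overlap-add reconstruction. All band filtering in the package
# (fixed notch, moving notch, equalizer gains) is applied as zero-phase
# per-bin gain masks on these frames.

#' STFT analysis parameters
#'
#' Window length is 4096 samples at the 44.1 kHz reference rate (~93 ms) and
#' scales with the sample rate, rounded to the nearest power of two; the hop
#' is a quarter window (75 % overlap). The resulting bin spacing
#' (~10.8 Hz at 44.1 kHz) resolves a half-octave notch at 1 kHz with margin.
#'
#' @param rate Sample rate in Hz.
#' @return List with `n` (window/FFT length), `hop` (samples), `window`
#'   (Hann), `freqs` (bin center frequencies, Hz), `hop_s` (hop in seconds).
#' @export
stft_params <- function(rate) {
  n <- 2^round(log2(4096 * rate / 44100))
  hop <- n %/% 4L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n) # periodic Hann
  list(
    n = n, hop = hop, window = w,
    freqs = (0:(n / 2)) * rate / n,
    hop_s = hop / rate
  )
}

# Process one channel with a per-frame gain mask.
#
# mask_fn(frame_index, time_s) must return a linear gain vector over
# p$freqs (length n/2 + 1). Analysis and synthesis both use the Hann
# window; the output is normalized by the overlap-added squared window so
# reconstruction is exact when all gains are 1.
stft_apply <- function(x, rate, mask_fn, p = stft_params(rate)) {
  n <- p$n
  hop <- p$hop
  w <- p$window
  len <- length(x)
  # pad so every sample is covered by a full set of overlapping windows
  pad <- n
  xp <- c(numeric(pad), x, numeric(pad + n))
  n_frames <- (length(xp) - n) %/% hop + 1L
  out <- numeric(length(xp))
  norm <- numeric(length(xp))
  half <- n %/% 2L + 1L
  last_mask <- NULL
  full_gain <- numeric(n)
  for (k in seq_len(n_frames)) {
    i0 <- (k - 1L) * hop
    frame_time <- (i0 + n / 2 - pad) / rate
    g <- mask_fn(k, frame_time)
    if (is.null(last_mask) || !identical(g, last_mask)) {
      full_gain[seq_len(half)] <- g
      if (n > 2L) full_gain[(half + 1L):n] <- rev(g[2:(half - 1L)])
      last_mask <- g
    }
    idx <- (i0 + 1L):(i0 + n)
    spec <- stats::fft(xp[idx] * w)
    y <- Re(stats::fft(spec * full_gain, inverse = TRUE)) / n
    out[idx] <- out[idx] + y * w
    norm[idx] <- norm[idx] + w^2
  }
  good <- norm > 1e-12
  out[good] <- out[good] / norm[good]
  out[(pad + 1L):(pad + len)]
}

# Apply a gain mask (static vector, or function of frame time) to every
# channel of a buffer identically.
apply_mask <- function(buffer, mask, p = stft_params(buffer$rate)) {
  mask_fn <- if (is.function(mask)) {
    mask
  } else {
    force(mask)
    function(k, t) mask
  }
  y <- apply(buffer$samples, 2L, function(ch) {
    stft_apply(ch, buffer$rate, mask_fn, p)
  })
  audio_buffer(y, buffer$rate)
}

#' Welch-averaged power spectral density
#'
#' Hann-windowed, 50 %-overlap averaged periodograms; channels are averaged.
#' Used by [estimate_ltas()] and [measure_response()].
#'
#' @param x An [audio_buffer()].
#' @param n Segment/FFT length (default 4096).
#' @return List with `freqs` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, n = 4096L) {
  stopifnot(inherits(x, "audio_buffer"))
  if (n_samples(x) < n) stop("signal shorter than one analysis window")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
  u <- sum(w^2)
  hop <- n %/% 2L
  half <- n %/% 2L + 1L
  acc <- numeric(half)
  n_seg <- 0L
  for (ch in seq_len(n_channels(x))) {
    s <- x$samples[, ch]
    starts <- seq(1L, length(s) - n + 1L, by = hop)
    for (i0 in starts) {
      spec <- stats::fft(s[i0:(i0 + n - 1L)] * w)
      acc <- acc + (Mod(spec[seq_len(half)])^2)
      n_seg <- n_seg + 1L
    }
  }
  psd <- acc / n_seg / (u * x$rate)
  psd[2:(half - 1L)] <- 2 * psd[2:(half - 1L)] # one-sided
  list(freqs = (0:(n %/% 2L)) * x$rate / n, psd = psd)
}

#' Measure a processor's magnitude response
#'
#' Per-frequency output-minus-input level from Welch-averaged power spectra
#' of the two buffers. Bins where the input has (near) zero power are
#' reported at the floor value rather than -Inf.
#'
#' @param input,output [audio_buffer()]s of equal rate and length.
#' @param n Welch segment length.
#' @param floor_db Reported gain floor for fully removed / empty bins.
#' @return A `magnitude_response`: data.frame with `freqs_hz`, `gain_db`.
#' @export
measure_response <- function(input, output, n = 4096L, floor_db = -120) {
  if (!isTRUE(all.equal(input$rate, output$rate))) {
    stop("input and output rates differ")
  }
  if (n_samples(input) != n_samples(output)) {
    stop("input and output lengths differ")
  }
  pi_ <- welch_psd(input, n)
  po <- welch_psd(output, n)
  eps <- max(pi_$psd) * 1e-14
  gain <- 10 * log10(pmax(po$psd, eps) / pmax(pi_$psd, eps))
  gain[pi_$psd <= eps] <- floor_db
  gain <- pmax(gain, floor_db)
  structure(
    data.frame(freqs_hz = pi_$freqs, gain_db = gain),
    class = c("magnitude_response", "data.frame")
  )
}
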