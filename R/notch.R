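#' Notch filter specification
#'
#' Parameters of the target-condition filter: a band of `notch_width_oct`
#' octaves centered at the tinnitus frequency is removed entirely (bin gain
#' 0), and the flanking bands of `edge_width_oct` octaves on each side are
#' amplified by `edge_gain_db` to strengthen lateral inhibition of the
#' neurons coding the notched frequencies. Region boundaries are smoothed
#' with a raised-cosine transition of `transition_oct` octaves to limit
#' ringing.
#'
#' @param center_hz Notch center frequency (the matched tinnitus pitch), Hz.
#' @param notch_width_oct Stop-band width in octaves (default 1/2).
#' @param edge_width_oct Width of each amplified edge band, octaves
#'   (default 3/8).
#' @param edge_gain_db Edge-band amplification in dB (default +20).
#' @param transition_oct Raised-cosine transition width in octaves
#'   (default 1/48).
#' @return A `notch_spec`.
#' @examples
#' notch_band(notch_spec(4000)) # c(3363.6, 4756.8)
#' @export
notch_spec <- function(center_hz, notch_width_oct = 0.5,
                       edge_width_oct = 0.375, edge_gain_db = 20,
                       transition_oct = 1 / 48) {
  stopifnot(
    is.numeric(center_hz), length(center_hz) == 1L, center_hz > 0,
    notch_width_oct > 0, edge_width_oct >= 0, transition_oct >= 0
  )
  if (transition_oct > min(notch_width_oct, max(edge_width_oct, notch_width_oct))) {
    stop("transition_oct must not exceed the bands it separates")
  }
  structure(
    list(
      center_hz = center_hz, notch_width_oct = notch_width_oct,
      edge_width_oct = edge_width_oct, edge_gain_db = edge_gain_db,
      transition_oct = transition_oct
    ),
    class = "notch_spec"
  )
}

#' @export
print.notch_spec <- function(x, ...) {
  nb <- notch_band(x)
  cat(sprintf(
    "<notch_spec> center %g Hz, stop band [%.1f, %.1f] Hz (%.3g oct), edges %.3g oct @ %+g dB\n",
    x$center_hz, nb[1], nb[2], x$notch_width_oct, x$edge_width_oct,
    x$edge_gain_db
  ))
  invisible(x)
}

#' @rdname notch_spec
#' @param spec A `notch_spec`.
#' @return `notch_band()`: the stop band `c(low, high)` in Hz,
#'   `center * 2^(+/- width/2)`.
#' @export
notch_band <- function(spec) {
  spec$center_hz * 2^(c(-1, 1) * spec$notch_width_oct / 2)
}

#' @rdname notch_spec
#' @return `edge_bands()`: list with `lower` and `upper` edge bands in Hz.
#' @export
edge_bands <- function(spec) {
  nb <- notch_band(spec)
  list(
    lower = nb[1] * 2^(c(-spec$edge_width_oct, 0)),
    upper = nb[2] * 2^(c(0, spec$edge_width_oct))
  )
}

#' Equalizer specification
#'
#' Parameters of the spectral equalization step, which redistributes energy
#' from low to high frequencies so that spectral power below and above the
#' notch is comparable. A single static gain curve is derived from the
#' long-term average spectrum (LTAS) of the whole track.
#'
#' @param band_resolution Analysis bandwidth as a fraction of an octave
#'   (default 1/3 octave).
#' @param range_hz Analysis/equalization limits, Hz (default 100-16000).
#' @param max_gain_db Per-band gain clamp in dB (default 24, applied as
#'   +/- `max_gain_db`).
#' @param preserve_energy Rescale the output to the input RMS (default TRUE).
#' @return An `eq_spec`.
#' @export
eq_spec <- function(band_resolution = 1 / 3, range_hz = c(100, 16000),
                    max_gain_db = 24, preserve_energy = TRUE) {
  stopifnot(
    band_resolution > 0, length(range_hz) == 2L,
    range_hz[1] > 0, range_hz[1] < range_hz[2], max_gain_db > 0
  )
  structure(
    list(
      band_resolution = band_resolution, range_hz = range_hz,
      max_gain_db = max_gain_db, preserve_energy = isTRUE(preserve_energy)
    ),
    class = "eq_spec"
  )
}

# raised-cosine interpolation of linear gains between region levels,
# evaluated in log2-frequency
rc_blend <- function(u) 0.5 - 0.5 * cos(pi * pmin(pmax(u, 0), 1))

#' Per-frequency gain mask of the notch + edge-enhancement filter
#'
#' Builds the linear gain applied per frequency bin: 0 strictly inside the
#' stop band, `10^(edge_gain_db/20)` inside each edge band, 1 elsewhere,
#' with raised-cosine transitions of `transition_oct` octaves centered on
#' each band boundary.
#'
#' @param spec A [notch_spec()].
#' @param freq_grid Positive, strictly increasing frequencies in Hz (bin
#'   centers; a leading DC bin at 0 Hz is accepted and passed through with
#'   gain 1).
#' @return Numeric vector of linear gains, one per grid frequency.
#' @export
design_notch_mask <- function(spec, freq_grid) {
  stopifnot(inherits(spec, "notch_spec"))
  pos <- freq_grid[freq_grid > 0]
  if (any(diff(freq_grid) <= 0) || length(pos) == 0L) {
    stop("freq_grid must be strictly increasing with positive frequencies")
  }
  eb <- edge_bands(spec)
  lo_limit <- eb$lower[1] * 2^(-spec$transition_oct / 2)
  hi_limit <- eb$upper[2] * 2^(spec$transition_oct / 2)
  if (lo_limit <= min(pos) || hi_limit >= max(freq_grid)) {
    stop(sprintf(
      "filter bands [%.1f, %.1f] Hz do not fit inside the frequency grid (%.1f-%.1f Hz); center %g Hz is too low or too high",
      lo_limit, hi_limit, min(pos), max(freq_grid), spec$center_hz
    ))
  }
  x <- suppressWarnings(log2(freq_grid / spec$center_hz)) # octaves from center
  n2 <- spec$notch_width_oct / 2
  e <- spec$edge_width_oct
  t2 <- spec$transition_oct / 2
  g_edge <- 10^(spec$edge_gain_db / 20)

  gain <- numeric(length(x))
  ax <- abs(x)
  # regions by |octaves from center|, outermost first
  gain[ax >= n2 + e + t2] <- 1
  if (e > 0) {
    tr <- ax > n2 + e - t2 & ax < n2 + e + t2 # edge outer boundary
    gain[tr] <- g_edge + (1 - g_edge) * rc_blend((ax[tr] - (n2 + e - t2)) / (2 * t2))
    gain[ax <= n2 + e - t2 & ax >= n2 + t2] <- g_edge
    inner_level <- g_edge
  } else {
    gain[ax >= n2 + t2] <- 1
    inner_level <- 1
  }
  tr <- ax < n2 + t2 & ax > n2 - t2 # notch boundary
  gain[tr] <- inner_level * (1 - rc_blend((ax[tr] - (n2 - t2)) / (2 * t2)))
  gain[ax <= n2 - t2] <- 0
  gain[!is.finite(x)] <- 1 # DC bin
  gain
}

# 1/x-octave band edges covering [low, high]
ltas_bands <- function(spec) {
  k <- spec$band_resolution
  n_bands <- ceiling(log2(spec$range_hz[2] / spec$range_hz[1]) / k)
  lo <- spec$range_hz[1] * 2^(k * (seq_len(n_bands) - 1L))
  hi <- pmin(lo * 2^k, spec$range_hz[2])
  data.frame(low_hz = lo, high_hz = hi, center_hz = sqrt(lo * hi))
}

#' Long-term average spectrum in fractional-octave bands
#'
#' Welch-averaged PSD summarized per band. The reported level is the dB of
#' the mean power per Hz within the band (so white noise measures flat);
#' the band's total energy reading is `level_db + 10*log10(bandwidth)`.
#'
#' @param signal An [audio_buffer()].
#' @param spec An [eq_spec()].
#' @return Data frame with one row per band: `low_hz`, `high_hz`,
#'   `center_hz`, `level_db`. Attribute `silent` is TRUE when the input had
#'   no measurable energy (all levels at the -120 dB floor).
#' @export
estimate_ltas <- function(signal, spec = eq_spec()) {
  psd <- welch_psd(signal)
  bands <- ltas_bands(spec)
  lev <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- psd$freqs >= bands$low_hz[i] & psd$freqs < bands$high_hz[i]
    if (!any(sel)) return(NA_real_)
    10 * log10(max(mean(psd$psd[sel]), 1e-30))
  }, numeric(1))
  lev[is.na(lev)] <- -300
  silent <- all(lev <= -120)
  if (silent) lev <- pmax(lev, -120)
  out <- cbind(bands, level_db = lev)
  attr(out, "silent") <- silent
  out
}

# static equalizer gain curve (dB at band centers -> linear per-bin gains)
eq_gain_curve <- function(ltas, spec, freqs) {
  lev <- ltas$level_db
  # energy-weighted mean level: weight each band by its total energy
  bw <- ltas$high_hz - ltas$low_hz
  energy <- 10^(lev / 10) * bw
  target <- 10 * log10(sum(energy) / sum(bw))
  gains_db <- pmin(pmax(target - lev, -spec$max_gain_db), spec$max_gain_db)
  # linear interpolation in log-frequency, constant inside the range,
  # rolled off to 0 dB over one analysis bandwidth outside it
  lf <- log2(ltas$center_hz)
  interp <- function(f) {
    g <- stats::approx(lf, gains_db, xout = log2(pmax(f, 1e-6)), rule = 2)$y
    fade_lo <- rc_blend(log2(pmax(f, 1e-6) / (spec$range_hz[1] * 2^-spec$band_resolution)) / spec$band_resolution)
    fade_hi <- 1 - rc_blend(log2(pmax(f, 1e-6) / spec$range_hz[2]) / spec$band_resolution)
    g * pmin(fade_lo, fade_hi)
  }
  10^(interp(freqs) / 20)
}

#' Equalize the energy spectrum of a signal
#'
#' Flattens the long-term average spectrum across the analysis range by
#' applying one static per-band gain curve (toward the energy-weighted mean
#' band level, clamped to +/- `max_gain_db`, interpolated linearly in log
#' frequency). With `preserve_energy`, output RMS is rescaled to the input
#' RMS.
#'
#' @param signal An [audio_buffer()].
#' @param spec An [eq_spec()].
#' @return The equalized [audio_buffer()].
#' @export
equalize <- function(signal, spec = eq_spec()) {
  ltas <- estimate_ltas(signal, spec)
  if (isTRUE(attr(ltas, "silent"))) return(signal)
  p <- stft_params(signal$rate)
  mask <- eq_gain_curve(ltas, spec, p$freqs)
  out <- apply_mask(signal, mask, p)
  if (spec$preserve_energy) {
    r_in <- rms(signal)
    r_out <- rms(out)
    if (r_out > 0) out$samples <- out$samples * (r_in / r_out)
  }
  out
}

#' Target-condition processing chain
#'
#' Applies the three-step tailor-made notched music modification: the track
#' is first equalized, then the half-octave band centered at the
#' individual tinnitus frequency is removed, and the 3/8-octave bands at
#' each notch edge are amplified by +20 dB. Both channels are processed
#' identically.
#'
#' @param signal An [audio_buffer()] with `rate >= 32000`.
#' @param tinnitus_hz Matched tinnitus frequency in Hz. The trial's
#'   inclusion range is 1-12 kHz; values outside it are rejected unless
#'   `force = TRUE`.
#' @param eq An [eq_spec()].
#' @param notch A [notch_spec()]; its center is overridden by
#'   `tinnitus_hz`.
#' @param force Process an out-of-range tinnitus frequency anyway.
#' @return The processed [audio_buffer()].
#' @export
process_target <- function(signal, tinnitus_hz, eq = eq_spec(),
                           notch = notch_spec(tinnitus_hz), force = FALSE) {
  stopifnot(inherits(signal, "audio_buffer"))
  if (!force && (tinnitus_hz < 1000 || tinnitus_hz > 12000)) {
    stop("tinnitus_hz outside the 1-12 kHz inclusion range; use force = TRUE to override")
  }
  if (signal$rate < 32000) {
    stop("sample rate below 32 kHz leaves no Nyquist margin for the upper edge band")
  }
  notch$center_hz <- tinnitus_hz
  eqd <- equalize(signal, eq)
  p <- stft_params(signal$rate)
  mask <- design_notch_mask(notch, p$freqs)
  apply_mask(eqd, mask, p)
}

#' Measure notch geometry from a magnitude response
#'
#' QC summary of a measured [measure_response()] curve against a
#' [notch_spec()]: the -6 dB stop-band width, each edge band's amplified
#' width (between half-edge-gain crossings), the mean gain over each edge
#' band's interior (transitions excluded), and the stop-band floor. Gains
#' are referenced to the measured passband level (median gain outside all
#' bands).
#'
#' @param resp A `magnitude_response`.
#' @param spec The [notch_spec()] the processing used.
#' @return List: `passband_db`, `stop_width_oct`, `edge_width_low_oct`,
#'   `edge_width_high_oct`, `edge_gain_low_db`, `edge_gain_high_db`,
#'   `floor_db`.
#' @export
measure_notch_geometry <- function(resp, spec) {
  f <- resp$freqs_hz
  g <- resp$gain_db
  eb <- edge_bands(spec)
  nb <- notch_band(spec)
  outside <- f > 0 & (f < eb$lower[1] * 2^-0.1 | f > eb$upper[2] * 2^0.1)
  pass <- stats::median(g[outside & f > 200 & f < 0.9 * max(f)])
  grel <- g - pass

  cross_width <- function(lo, hi, level, rising_first) {
    sel <- which(f >= lo & f <= hi)
    x <- log2(f[sel])
    y <- grel[sel]
    cr <- function(i) { # linear interp of crossing between i, i+1
      x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
    }
    idx_up <- which(y[-length(y)] < level & y[-1] >= level)
    idx_dn <- which(y[-length(y)] >= level & y[-1] < level)
    if (length(idx_up) == 0L || length(idx_dn) == 0L) return(NA_real_)
    if (rising_first) cr(idx_dn[length(idx_dn)]) - cr(idx_up[1])
    else cr(idx_up[length(idx_up)]) - cr(idx_dn[1])
  }

  # -6 dB stop-band width: crossings of -6 dB between the two edge bands
  stop_w <- cross_width(nb[1] * 2^-0.2, nb[2] * 2^0.2, -6, rising_first = FALSE)
  half_edge <- spec$edge_gain_db / 2
  t2 <- spec$transition_oct
  edge_interior <- function(band) {
    sel <- f >= band[1] * 2^t2 & f <= band[2] * 2^-t2
    mean(grel[sel])
  }
  notch_interior <- f >= nb[1] * 2^t2 & f <= nb[2] * 2^-t2
  list(
    passband_db = pass,
    stop_width_oct = stop_w,
    edge_width_low_oct = cross_width(eb$lower[1] * 2^-0.1, eb$lower[2] * 2^0.15,
                                     half_edge, rising_first = TRUE),
    edge_width_high_oct = cross_width(eb$upper[1] * 2^-0.15, eb$upper[2] * 2^0.1,
                                      half_edge, rising_first = TRUE),
    edge_gain_low_db = edge_interior(eb$lower),
    edge_gain_high_db = edge_interior(eb$upper),
    floor_db = min(grel[notch_interior])
  )
}
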