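#' Cent / Hertz conversion
#'
#' Pitch is averaged on the logarithmic Cent scale (1 Cent = 1/1200 octave):
#' `c = 1200 * log2(f / ref)`. The package-wide default reference is
#' 1000 Hz (the low end of the matching range); the reference cancels in
#' all aggregated Hz results.
#'
#' @param f,c Frequency in Hz / pitch in cents.
#' @param ref Reference frequency in Hz.
#' @return Cents, or Hz for the inverse.
#' @examples
#' hz_to_cents(2000, 1000) # 1200 (one octave)
#' @export
hz_to_cents <- function(f, ref = 1000) {
  stopifnot(all(f > 0), ref > 0)
  1200 * log2(f / ref)
}

#' @rdname hz_to_cents
#' @export
cents_to_hz <- function(c, ref = 1000) {
  stopifnot(ref > 0)
  ref * 2^(c / 1200)
}

#' Frequency interval
#' @param low_hz,high_hz Interval bounds in Hz, `0 < low < high`.
#' @return A `freq_interval`.
#' @export
freq_interval <- function(low_hz, high_hz) {
  stopifnot(low_hz > 0, high_hz > low_hz)
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "freq_interval")
}

#' @rdname freq_interval
#' @param iv A `freq_interval`.
#' @return `interval_width_oct()`: width in octaves; `interval_mid()`: the
#'   geometric (log-frequency) midpoint in Hz.
#' @export
interval_width_oct <- function(iv) log2(iv$high_hz / iv$low_hz)

#' @rdname freq_interval
#' @export
interval_mid <- function(iv) sqrt(iv$low_hz * iv$high_hz)

#' Bisect a frequency interval at the log midpoint
#'
#' "Equally large" subintervals are equal in octaves, so the split point is
#' the geometric mean of the bounds and each half has half the parent's
#' octave width.
#'
#' @param iv A [freq_interval()].
#' @return List with `low` and `high` subintervals.
#' @export
bisect_interval <- function(iv) {
  m <- interval_mid(iv)
  list(low = freq_interval(iv$low_hz, m), high = freq_interval(m, iv$high_hz))
}

#' Matching configuration
#'
#' @param range_hz Search range, Hz (default 1-16 kHz).
#' @param stop_width_oct Terminate when the interval is at most this wide
#'   (default 1/12 octave).
#' @param max_rounds Hard round cap (default 12).
#' @param octave_test Run the downward octave-confusion check on the
#'   matched frequency (default TRUE).
#' @param cents_ref Reference frequency for Cent values (default 1000 Hz).
#' @return A `match_config`.
#' @export
match_config <- function(range_hz = c(1000, 16000), stop_width_oct = 1 / 12,
                         max_rounds = 12L, octave_test = TRUE,
                         cents_ref = 1000) {
  stopifnot(
    length(range_hz) == 2L, range_hz[1] > 0, range_hz[1] < range_hz[2],
    stop_width_oct > 0, max_rounds >= 1L
  )
  structure(
    list(
      range_hz = range_hz, stop_width_oct = stop_width_oct,
      max_rounds = as.integer(max_rounds), octave_test = isTRUE(octave_test),
      cents_ref = cents_ref
    ),
    class = "match_config"
  )
}

#' Simulated forced-choice listener
#'
#' Stand-in for a participant in the pitch-matching procedure. On each
#' two-interval forced-choice trial the listener compares the two
#' presented tones against an internal pitch perceived with Gaussian noise
#' on the Cent scale, and with probability `lapse_rate` answers at random.
#'
#' @param true_hz The listener's true tinnitus pitch in Hz.
#' @param noise_cents SD of the per-trial judgment noise, cents.
#' @param lapse_rate Probability of a random choice, in `[0, 0.5)`.
#' @param cents_ref Cent reference frequency.
#' @return A `sim_listener`.
#' @export
sim_listener <- function(true_hz, noise_cents = 50, lapse_rate = 0.02,
                         cents_ref = 1000) {
  stopifnot(true_hz > 0, noise_cents >= 0)
  if (lapse_rate < 0 || lapse_rate >= 0.5) {
    stop("lapse_rate must be in [0, 0.5)")
  }
  structure(
    list(
      true_pitch_cents = hz_to_cents(true_hz, cents_ref),
      judgment_noise_cents = noise_cents, lapse_rate = lapse_rate,
      cents_ref = cents_ref
    ),
    class = "sim_listener"
  )
}

# one 2-IFC trial: which end of [low_hz, high_hz] is more similar to the
# (noisily perceived) tinnitus pitch?
listener_choose <- function(listener, low_hz, high_hz) {
  if (stats::runif(1) < listener$lapse_rate) {
    return(sample(c("low_end", "high_end"), 1L))
  }
  perceived <- listener$true_pitch_cents +
    stats::rnorm(1, 0, listener$judgment_noise_cents)
  d_low <- abs(hz_to_cents(low_hz, listener$cents_ref) - perceived)
  d_high <- abs(hz_to_cents(high_hz, listener$cents_ref) - perceived)
  if (d_low <= d_high) "low_end" else "high_end"
}

#' Interval update rule of the recursive 2-IFC procedure
#'
#' Each round asks two forced-choice questions, one per subinterval:
#' whether the tinnitus is more similar to the lower or the higher end.
#' Consistent answers recurse into the low subinterval, the high
#' subinterval, or the middle interval bounded by the two subinterval
#' (log) midpoints; the `(low_end, high_end)` pattern is inconsistent and
#' is handled by the session driver (repeat once, then fall back to the
#' middle interval).
#'
#' @param choice_low Choice on the low subinterval trial: `"low_end"` or
#'   `"high_end"`.
#' @param choice_high Choice on the high subinterval trial.
#' @param iv The current [freq_interval()].
#' @return List: `interval` (the next [freq_interval()]) and `pattern`
#'   (`"low"`, `"high"`, `"middle"`, or `"inconsistent"` — which also maps
#'   to the middle interval).
#' @export
next_interval <- function(choice_low, choice_high, iv) {
  choice_low <- match.arg(choice_low, c("low_end", "high_end"))
  choice_high <- match.arg(choice_high, c("low_end", "high_end"))
  subs <- bisect_interval(iv)
  middle <- freq_interval(interval_mid(subs$low), interval_mid(subs$high))
  if (choice_low == "low_end" && choice_high == "low_end") {
    list(interval = subs$low, pattern = "low")
  } else if (choice_low == "high_end" && choice_high == "high_end") {
    list(interval = subs$high, pattern = "high")
  } else if (choice_low == "high_end" && choice_high == "low_end") {
    list(interval = middle, pattern = "middle")
  } else {
    list(interval = middle, pattern = "inconsistent")
  }
}

#' Downward octave-confusion check
#'
#' Final forced choice of a matching session: the matched frequency is
#' played against the tone one octave below, and the listener keeps
#' whichever is closer to the perceived pitch. Screens the common
#' one-octave-high matching error.
#'
#' @param listener A [sim_listener()].
#' @param matched_hz The candidate matched frequency.
#' @param min_hz Lowest presentable frequency; if `matched_hz / 2` falls
#'   below it the check is skipped.
#' @return The retained frequency (`matched_hz` or `matched_hz / 2`).
#' @export
octave_confusion <- function(listener, matched_hz, min_hz = 20) {
  stopifnot(matched_hz > 0)
  if (matched_hz / 2 < min_hz) return(matched_hz)
  choice <- listener_choose(listener, matched_hz / 2, matched_hz)
  if (choice == "low_end") matched_hz / 2 else matched_hz
}

#' Run one pitch-matching session
#'
#' Recursive two-interval forced-choice estimation of the tinnitus
#' frequency: the range is bisected on the log axis, the listener judges
#' both subintervals, and the procedure recurses per [next_interval()]
#' until the interval is at most `stop_width_oct` wide or `max_rounds` is
#' reached. The matched frequency is the geometric midpoint of the final
#' interval, optionally screened by [octave_confusion()]. Every choice is
#' recorded.
#'
#' @param listener A [sim_listener()].
#' @param cfg A [match_config()].
#' @param seed Integer seed making the session reproducible.
#' @param loudness Loudness setting the participant chose for the test
#'   tones (a saved scalar; not modeled further).
#' @return A `pitch_session`: `matched_hz`, `matched_cents`,
#'   `loudness_setting`, `rounds_used`, `responses` (data.frame `round`,
#'   `low_hz`, `high_hz`, `choice_low`, `choice_high`, `pattern`).
#' @export
run_session <- function(listener, cfg = match_config(), seed = NULL,
                        loudness = NA_real_) {
  stopifnot(inherits(listener, "sim_listener"))
  with_seed(seed, {
    iv <- freq_interval(cfg$range_hz[1], cfg$range_hz[2])
    rows <- list()
    round <- 0L
    while (interval_width_oct(iv) > cfg$stop_width_oct &&
             round < cfg$max_rounds) {
      round <- round + 1L
      subs <- bisect_interval(iv)
      ask <- function() {
        c(
          listener_choose(listener, subs$low$low_hz, subs$low$high_hz),
          listener_choose(listener, subs$high$low_hz, subs$high$high_hz)
        )
      }
      ch <- ask()
      res <- next_interval(ch[1], ch[2], iv)
      if (res$pattern == "inconsistent") { # repeat the round once
        ch <- ask()
        res <- next_interval(ch[1], ch[2], iv)
      }
      rows[[round]] <- data.frame(
        round = round, low_hz = iv$low_hz, high_hz = iv$high_hz,
        choice_low = ch[1], choice_high = ch[2], pattern = res$pattern
      )
      iv <- res$interval
    }
    matched <- interval_mid(iv)
    if (cfg$octave_test) matched <- octave_confusion(listener, matched)
    matched <- min(max(matched, cfg$range_hz[1]), cfg$range_hz[2])
    structure(
      list(
        matched_hz = matched,
        matched_cents = hz_to_cents(matched, cfg$cents_ref),
        loudness_setting = loudness,
        rounds_used = round,
        responses = do.call(rbind, rows)
      ),
      class = "pitch_session"
    )
  })
}

#' @export
print.pitch_session <- function(x, ...) {
  cat(sprintf(
    "<pitch_session> matched %.1f Hz (%.1f cents re 1 kHz) in %d rounds\n",
    x$matched_hz, x$matched_cents, x$rounds_used
  ))
  invisible(x)
}

#' Aggregate repeated pitch-matching sessions
#'
#' The protocol runs the matching twice a day for five days; the final
#' tinnitus frequency is the arithmetic mean of the ten matches on the
#' Cent scale (equivalently the geometric mean in Hz), and the
#' per-participant SD of the matches quantifies pitch-matching
#' variability.
#'
#' @param sessions List of `pitch_session` objects (or a numeric vector of
#'   matched frequencies in Hz).
#' @param cents_ref Cent reference frequency.
#' @return A `pitch_estimate`: `mean_cents`, `sd_cents`, `mean_hz`,
#'   `n_sessions`.
#' @export
aggregate_sessions <- function(sessions, cents_ref = 1000) {
  hz <- if (is.numeric(sessions)) {
    sessions
  } else {
    vapply(sessions, function(s) s$matched_hz, numeric(1))
  }
  if (length(hz) < 1L) stop("at least one session is required")
  cents <- hz_to_cents(hz, cents_ref)
  m <- mean(cents)
  structure(
    list(
      mean_cents = m,
      sd_cents = if (length(cents) > 1L) stats::sd(cents) else 0,
      mean_hz = cents_to_hz(m, cents_ref),
      n_sessions = length(cents)
    ),
    class = "pitch_estimate"
  )
}

#' @export
print.pitch_estimate <- function(x, ...) {
  cat(sprintf(
    "<pitch_estimate> %.1f Hz (mean of %d sessions; SD %.1f cents)\n",
    x$mean_hz, x$n_sessions, x$sd_cents
  ))
  invisible(x)
}
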