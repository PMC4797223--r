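#' Moving-notch placebo filter state
#'
#' State of the placebo condition's random-walk notch: a filter of the same
#' bandwidth as the target notch sits at `center_hz` and, after every
#' `dwell_s` seconds of filtering, jumps `step_oct` octaves in its current
#' direction. The first direction is drawn at random; thereafter the notch
#' keeps moving the same way until its band edge would cross a predefined
#' border, at which point the direction reverses and the step is taken the
#' other way.
#'
#' @param center_hz Current notch center, Hz.
#' @param direction `"up"`, `"down"`, or `NA` (drawn uniformly at random on
#'   the first jump).
#' @param dwell_s Seconds of filtering between jumps (default 5).
#' @param step_oct Jump size in octaves (default 1/18).
#' @param border_hz Reflection borders `c(low, high)` for the notch band
#'   edges (default `c(1000, 16000)`, the pitch-matching range).
#' @param notch_width_oct Width of the notch the state drives, octaves.
#' @param elapsed_s Filtering time accumulated since the last jump.
#' @return A `moving_notch_state`.
#' @export
moving_notch_state <- function(center_hz, direction = NA_character_,
                               dwell_s = 5, step_oct = 1 / 18,
                               border_hz = c(1000, 16000),
                               notch_width_oct = 0.5, elapsed_s = 0) {
  stopifnot(
    center_hz > 0, dwell_s > 0, step_oct > 0,
    length(border_hz) == 2L, border_hz[1] > 0, border_hz[1] < border_hz[2],
    notch_width_oct > 0, elapsed_s >= 0
  )
  if (!is.na(direction)) direction <- match.arg(direction, c("up", "down"))
  border_oct <- log2(border_hz[2] / border_hz[1])
  if (border_oct < notch_width_oct + 2 * step_oct) {
    stop("borders narrower than the notch band plus two steps; the walk cannot move")
  }
  half <- notch_width_oct / 2
  if (center_hz * 2^-half < border_hz[1] || center_hz * 2^half > border_hz[2]) {
    stop("notch band extends beyond the borders at this center frequency")
  }
  structure(
    list(
      center_hz = center_hz, direction = direction, dwell_s = dwell_s,
      step_oct = step_oct, border_hz = border_hz,
      notch_width_oct = notch_width_oct, elapsed_s = elapsed_s
    ),
    class = "moving_notch_state"
  )
}

#' @export
print.moving_notch_state <- function(x, ...) {
  cat(sprintf(
    "<moving_notch_state> center %.1f Hz, direction %s, %.2f/%g s into dwell, borders [%g, %g] Hz\n",
    x$center_hz, ifelse(is.na(x$direction), "(undrawn)", x$direction),
    x$elapsed_s, x$dwell_s, x$border_hz[1], x$border_hz[2]
  ))
  invisible(x)
}

#' Advance the moving-notch random walk
#'
#' Adds `dt_s` seconds of filtering time to the state's dwell clock and
#' commits a jump for every full dwell period that expires: the center is
#' multiplied by `2^(+/- step_oct)` in the current direction; if the
#' resulting notch band edge would cross a border, the direction is
#' reversed first and the step taken the other way (reflect-before-move,
#' so the band never leaves the borders). The first-ever jump direction is
#' drawn uniformly at random from the current RNG stream.
#'
#' @param state A [moving_notch_state()].
#' @param dt_s Elapsed filtering time to add, seconds (default one full
#'   dwell period).
#' @return The updated `moving_notch_state` (with `0 <= elapsed_s <
#'   dwell_s` after every committed step).
#' @export
moving_notch_step <- function(state, dt_s = state$dwell_s) {
  stopifnot(inherits(state, "moving_notch_state"), dt_s >= 0)
  state$elapsed_s <- state$elapsed_s + dt_s
  half <- state$notch_width_oct / 2
  while (state$elapsed_s >= state$dwell_s) {
    state$elapsed_s <- state$elapsed_s - state$dwell_s
    if (is.na(state$direction)) {
      state$direction <- sample(c("up", "down"), 1L)
    }
    sgn <- if (state$direction == "up") 1 else -1
    proposed <- state$center_hz * 2^(sgn * state$step_oct)
    crosses <- proposed * 2^(sgn * half) > state$border_hz[2] ||
      proposed * 2^(sgn * half) < state$border_hz[1]
    if (crosses) {
      state$direction <- if (state$direction == "up") "down" else "up"
      sgn <- -sgn
      proposed <- state$center_hz * 2^(sgn * state$step_oct)
    }
    state$center_hz <- proposed
  }
  state
}

#' Placebo-condition processing chain
#'
#' Same chain as [process_target()] (equalization, full notch removal, edge
#' enhancement) but with the notch center driven by the moving-notch random
#' walk: the initial center is drawn uniformly in log frequency within the
#' admissible range, and the center jumps `step_oct` octaves every
#' `dwell_s` seconds, reflecting at the borders. Jump instants are
#' quantized to STFT frame hops; the 75 %-overlap add itself crossfades
#' between the old and new masks across one window, so jumps are click-free.
#'
#' @param signal An [audio_buffer()] at least one dwell period long.
#' @param eq An [eq_spec()].
#' @param notch A [notch_spec()] providing bandwidth, edge width/gain and
#'   transition (its center is driven by the walk).
#' @param borders Reflection borders for the notch band edges, Hz.
#' @param seed Integer seed; the walk (initial center, first direction) is
#'   reproducible from it.
#' @param dwell_s,step_oct Walk timing and step size.
#' @return List with `audio` (processed [audio_buffer()]) and `trace`
#'   (data.frame `time_s`, `center_hz`, `direction`, one row per STFT
#'   frame).
#' @export
process_placebo <- function(signal, eq = eq_spec(), notch = notch_spec(4000),
                            borders = c(1000, 16000), seed = NULL,
                            dwell_s = 5, step_oct = 1 / 18) {
  stopifnot(inherits(signal, "audio_buffer"))
  if (duration_s(signal) < dwell_s) {
    stop("signal shorter than one dwell period; the notch would never move")
  }
  with_seed(seed, {
    half <- notch$notch_width_oct / 2
    admissible <- log2(c(borders[1] * 2^half, borders[2] * 2^-half))
    center0 <- 2^stats::runif(1L, admissible[1], admissible[2])
    state <- moving_notch_state(
      center_hz = center0, dwell_s = dwell_s, step_oct = step_oct,
      border_hz = borders, notch_width_oct = notch$notch_width_oct
    )
    eqd <- equalize(signal, eq)
    p <- stft_params(signal$rate)

    # precompute the walk frame-by-frame so both channels see identical masks
    n_frames <- (n_samples(signal) + 3L * p$n) %/% p$hop + 1L
    centers <- numeric(n_frames)
    dirs <- character(n_frames)
    for (k in seq_len(n_frames)) {
      centers[k] <- state$center_hz
      dirs[k] <- if (is.na(state$direction)) "undrawn" else state$direction
      state <- moving_notch_step(state, p$hop_s)
    }
    mask_cache <- new.env(parent = emptyenv())
    mask_for <- function(center) {
      key <- sprintf("%.9g", center)
      m <- mask_cache[[key]]
      if (is.null(m)) {
        sp <- notch
        sp$center_hz <- center
        m <- design_notch_mask(sp, p$freqs)
        mask_cache[[key]] <- m
      }
      m
    }
    mask_fn <- function(k, t) mask_for(centers[min(k, n_frames)])
    out <- audio_buffer(
      apply(eqd$samples, 2L, function(ch) stft_apply(ch, signal$rate, mask_fn, p)),
      signal$rate
    )
    frame_times <- (seq_len(n_frames) - 1L) * p$hop_s
    keep <- frame_times <= duration_s(signal)
    list(
      audio = out,
      trace = data.frame(
        time_s = frame_times[keep], center_hz = centers[keep],
        direction = dirs[keep]
      )
    )
  })
}

#' Jump summary of a placebo trace
#'
#' Extracts the committed jumps from a [process_placebo()] trace: times at
#' which the center changed, the inter-jump intervals, and the step
#' magnitudes in octaves.
#'
#' @param trace The `trace` data.frame from [process_placebo()].
#' @return List: `jump_times_s`, `intervals_s` (between successive jumps),
#'   `step_oct` (absolute log2 ratios of successive distinct centers).
#' @export
trace_jumps <- function(trace) {
  chg <- which(diff(trace$center_hz) != 0) + 1L
  list(
    jump_times_s = trace$time_s[chg],
    intervals_s = diff(trace$time_s[chg]),
    step_oct = abs(log2(trace$center_hz[chg] / trace$center_hz[chg - 1L]))
  )
}
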