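# Seeded generators for everything the other modules consume: music-like
# audio, measurement probes, and two-arm cohorts with controllable
# treatment effects. No recorded music or participant data ships with the
# package; every fixture is synthesized at run time.

#' Music surrogate model
#'
#' Stand-in for a participant's music library: spectrally tilted colored
#' noise (real music carries unequal energy across octaves, typically less
#' in the highs) plus a handful of amplitude-modulated harmonic tones.
#'
#' @param spectral_tilt_db_per_octave LTAS slope of the noise bed
#'   (default -3 dB/octave).
#' @param n_harmonic_tones Number of tone complexes (default 8).
#' @param tone_freq_range Fundamental range of the tones, Hz.
#' @param amplitude_modulation_rate Tremolo rate, Hz.
#' @param duration_s,rate Length and sample rate.
#' @return A `music_model`.
#' @export
music_model <- function(spectral_tilt_db_per_octave = -3,
                        n_harmonic_tones = 8L,
                        tone_freq_range = c(200, 4000),
                        amplitude_modulation_rate = 4,
                        duration_s = 30, rate = 44100) {
  stopifnot(
    duration_s > 0, rate >= 32000, n_harmonic_tones >= 0,
    tone_freq_range[1] > 0, tone_freq_range[2] < rate / 2
  )
  structure(
    list(
      spectral_tilt_db_per_octave = spectral_tilt_db_per_octave,
      n_harmonic_tones = as.integer(n_harmonic_tones),
      tone_freq_range = tone_freq_range,
      amplitude_modulation_rate = amplitude_modulation_rate,
      duration_s = duration_s, rate = rate
    ),
    class = "music_model"
  )
}

# noise with PSD sloping `tilt` dB per octave (0 = white), shaped in the
# frequency domain
tilted_noise <- function(n, rate, tilt, f_ref = 1000) {
  x <- stats::rnorm(n)
  if (tilt == 0) return(x)
  spec <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f) # fold to analog frequency
  shape <- 10^(tilt * log2(pmax(f, 1) / f_ref) / 20)
  shape[1] <- 0
  Re(stats::fft(spec * shape, inverse = TRUE)) / n
}

#' Generate music-like audio
#'
#' @param model A [music_model()].
#' @param seed Integer seed; the same `(model, seed)` always reproduces the
#'   identical buffer.
#' @return A mono [audio_buffer()] scaled to 0.1 RMS for peak headroom.
#' @export
make_music <- function(model = music_model(), seed = NULL) {
  stopifnot(inherits(model, "music_model"))
  with_seed(seed, {
    n <- round(model$duration_s * model$rate)
    t <- (seq_len(n) - 1) / model$rate
    x <- tilted_noise(n, model$rate, model$spectral_tilt_db_per_octave)
    x <- x / stats::sd(x)
    if (model$n_harmonic_tones > 0L) {
      lo <- log2(model$tone_freq_range[1])
      hi <- log2(model$tone_freq_range[2])
      f0 <- 2^stats::runif(model$n_harmonic_tones, lo, hi)
      phases <- stats::runif(model$n_harmonic_tones, 0, 2 * pi)
      am_ph <- stats::runif(model$n_harmonic_tones, 0, 2 * pi)
      tones <- numeric(n)
      for (i in seq_len(model$n_harmonic_tones)) {
        partial <- numeric(n)
        for (h in 1:3) { # three partials, rolling off
          fh <- f0[i] * h
          if (fh < model$rate / 2) {
            partial <- partial + sin(2 * pi * fh * t + phases[i] * h) / h
          }
        }
        am <- 1 + 0.5 * sin(2 * pi * model$amplitude_modulation_rate * t + am_ph[i])
        tones <- tones + partial * am
      }
      x <- x + 0.3 * tones / stats::sd(tones)
    }
    audio_buffer(0.1 * x / stats::sd(x), model$rate)
  })
}

#' Generate a measurement probe
#'
#' Probe signals for [measure_response()] verification: spectrally flat
#' Gaussian noise, an impulse train (line spectrum at multiples of the
#' repetition rate), or an exponential chirp sweeping 100 Hz to 16 kHz.
#'
#' @param kind `"flat_noise"`, `"impulse_train"` or `"chirp"`.
#' @param duration_s,rate Length and sample rate.
#' @param seed Integer seed (used by `flat_noise`).
#' @param rep_rate_hz Impulse-train repetition rate, Hz.
#' @return A mono [audio_buffer()].
#' @export
make_probe <- function(kind = c("flat_noise", "impulse_train", "chirp"),
                       duration_s = 30, rate = 44100, seed = NULL,
                       rep_rate_hz = 100) {
  kind <- match.arg(kind)
  n <- round(duration_s * rate)
  with_seed(seed, {
    x <- switch(kind,
      flat_noise = 0.1 * stats::rnorm(n),
      impulse_train = {
        x <- numeric(n)
        x[seq(1L, n, by = round(rate / rep_rate_hz))] <- 1
        x
      },
      chirp = {
        t <- (seq_len(n) - 1) / rate
        f0 <- 100
        f1 <- 16000
        k <- log(f1 / f0) / duration_s
        0.1 * sin(2 * pi * f0 * (exp(k * t) - 1) / k)
      }
    )
    audio_buffer(x, rate)
  })
}

#' Cohort model
#'
#' Two-arm trial cohort generator settings. Defaults mirror the study
#' population: age normal (mean 47.5, SD 10.8) truncated to 18-70 years,
#' hearing loss uniform on 0-70 dB, tinnitus pitch log-normal around
#' 5.4 kHz truncated to the 1-12 kHz inclusion range, and a 17 % dropout
#' rate after the pre session.
#'
#' @param n Cohort size (default 100).
#' @param dropout_rate Probability a participant drops out after `pre`.
#' @param arm_effects Named list `measure -> c(treatment = , placebo = )`
#'   mean change from pre applied at post and follow-up (default: no
#'   effect anywhere).
#' @param change_sd SD of the per-participant change noise around the arm
#'   mean change.
#' @param harm_rates Named vector of per-category harm probabilities
#'   applied to each respondent.
#' @return A `cohort_model`.
#' @export
cohort_model <- function(n = 100L, dropout_rate = 0.17, arm_effects = list(),
                         change_sd = 10,
                         harm_rates = c(
                           consistently_louder = 0.10, additional_sound = 0.08,
                           more_aware = 0.06, at_times_louder = 0.04
                         )) {
  stopifnot(n >= 2L, dropout_rate >= 0, dropout_rate <= 1, change_sd >= 0)
  structure(
    list(
      n = as.integer(n), dropout_rate = dropout_rate,
      arm_effects = arm_effects, change_sd = change_sd,
      harm_rates = harm_rates
    ),
    class = "cohort_model"
  )
}

# baseline means/SDs of the generated measures (0-100 VAS bounds enforced)
cohort_baselines <- function() {
  data.frame(
    measure = c(vas_subscales, "thq", "tq", "thi"),
    mean = c(50, 40, 55, 30, 27, 22, 25),
    sd = c(22, 24, 23, 22, 16, 12, 16),
    is_vas = c(rep(TRUE, 4L), rep(FALSE, 3L))
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic trial cohort
#'
#' Builds an eligible-by-construction roster, randomizes it with
#' [randomize_blocks()], and simulates the long outcome table over the four
#' sessions (baseline, pre, post, follow-up) plus a harms table. Arm
#' effects are injected as mean change scores at post/follow-up, so
#' parameter recovery via [change_score()] is exactly checkable; dropouts
#' are missing after `pre`.
#'
#' @param model A [cohort_model()].
#' @param seed Integer seed.
#' @return List: `roster`, `allocation`, `outcomes` (long table),
#'   `harms`.
#' @export
make_cohort <- function(model = cohort_model(), seed = NULL) {
  stopifnot(inherits(model, "cohort_model"))
  with_seed(seed, {
    n <- model$n
    roster <- data.frame(
      id = sprintf("P%03d", seq_len(n)),
      age = round(rtrunc_norm(n, 47.5, 10.8, 18, 70), 1),
      hearing_loss_db = round(stats::runif(n, 0, 70), 1),
      tinnitus_hz = round(2^rtrunc_norm(n, log2(5400), 0.45,
                                        log2(1000), log2(12000))),
      chronicity_months = round(stats::runif(n, 6, 240)),
      mental_disorder = FALSE, otological_disease = FALSE,
      substance_use = FALSE, concurrent_therapy = FALSE, consent = TRUE
    )
    alloc <- randomize_blocks(roster)
    dropped <- stats::runif(n) < model$dropout_rate

    base <- cohort_baselines()
    rows <- vector("list", n * nrow(base))
    r <- 0L
    for (i in seq_len(n)) {
      arm <- alloc$arm[i]
      for (j in seq_len(nrow(base))) {
        m <- base$measure[j]
        clamp <- function(v) {
          if (base$is_vas[j]) pmin(pmax(v, 0), 100) else pmax(v, 0)
        }
        b0 <- clamp(stats::rnorm(1, base$mean[j], base$sd[j]))
        eff <- if (!is.null(model$arm_effects[[m]])) {
          unname(model$arm_effects[[m]][[arm]])
        } else {
          0
        }
        pre <- clamp(b0 + stats::rnorm(1, 0, model$change_sd / 2))
        post <- clamp(pre + eff + stats::rnorm(1, 0, model$change_sd))
        fu <- clamp(pre + eff + stats::rnorm(1, 0, model$change_sd))
        vals <- c(b0, pre,
                  if (dropped[i]) NA_real_ else post,
                  if (dropped[i]) NA_real_ else fu)
        r <- r + 1L
        rows[[r]] <- data.frame(
          id = roster$id[i], arm = arm, session = outcome_sessions,
          measure = m, value = vals
        )
      }
    }
    outcomes <- do.call(rbind, rows[seq_len(r)])

    respondents <- roster$id[!dropped]
    harm_rows <- list()
    h <- 0L
    for (id in respondents) {
      arm <- alloc$arm[match(id, roster$id)]
      for (cat in names(model$harm_rates)) {
        if (stats::runif(1) < model$harm_rates[[cat]]) {
          h <- h + 1L
          harm_rows[[h]] <- data.frame(id = id, arm = arm, category = cat)
        }
      }
    }
    harms <- if (h > 0L) {
      do.call(rbind, harm_rows)
    } else {
      data.frame(id = character(), arm = character(), category = character())
    }
    list(
      roster = roster, allocation = alloc, outcomes = outcomes,
      harms = harms, respondents = respondents
    )
  })
}

#' Fit the LTAS slope of a buffer
#'
#' Least-squares slope of band level against log2 frequency, in dB per
#' octave. Used to verify generated spectra.
#'
#' @param x An [audio_buffer()].
#' @param spec An [eq_spec()] defining the analysis bands.
#' @return Slope in dB/octave.
#' @export
ltas_slope <- function(x, spec = eq_spec()) {
  l <- estimate_ltas(x, spec)
  unname(stats::coef(stats::lm(l$level_db ~ log2(l$center_hz)))[2])
}
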