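---
title: "Methods: notched music processing, pitch matching, and trial arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: notched music processing, pitch matching, and trial arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(notchkit)
```

`notchkit` packages the computational machinery of a tailor-made notched
music training (TMNMT) trial for tonal tinnitus: the audio modification
delivered to the treatment arm, the placebo filter, the self-administered
tinnitus pitch-matching procedure, and the design and outcome arithmetic
around them. This vignette explains the models and the choices behind
them; every number quoted here is computed by the package's test suite or
by `scripts/acceptance.R`.

## The notch filter model

The therapeutic premise is lateral inhibition: auditory neurons coding the
tinnitus frequency receive no afferent input while their spectral
neighbors are driven hard, so the neighbors' inhibitory projections
suppress the hyperactive region. The filter therefore has three parts,
all parameterized by `notch_spec()`:

* a **stop band** of `notch_width_oct` = ½ octave centered at the matched
  tinnitus frequency $f_t$, i.e. $[f_t 2^{-1/4}, f_t 2^{+1/4}]$, with bin
  gain exactly 0 — "removed" is implemented as total removal since no
  attenuation depth is part of the design, and total removal maximizes the
  intended input deprivation;
* two **edge bands** of `edge_width_oct` = 3/8 octave immediately flanking
  the stop band, amplified by `edge_gain_db` = +20 dB to boost the
  inhibitory drive;
* **raised-cosine transitions** of `transition_oct` = 1/48 octave centered
  on each band boundary. A hard 0/1 mask edge rings (Gibbs overshoot in the
  time domain); 1/48 octave is narrow against every band it separates yet
  wide enough (≈ 4 bins at 4 kHz) to suppress audible ringing.

Filtering runs in a short-time Fourier transform: Hann window of 4096
samples at the 44.1 kHz reference rate (~93 ms; the length scales with the
sample rate and snaps to a power of two), 75 % overlap, zero-phase per-bin
gain, Hann synthesis window, and normalization by the overlap-added
squared window. The 10.8 Hz bin spacing resolves a ½-octave notch at the
1 kHz bottom of the admissible range (width ≈ 293 Hz ≈ 27 bins) with
margin. Both stereo channels receive identical masks, so identical
channels stay bit-identical.

Measured on a 30 s flat-noise probe (`measure_notch_geometry()`), the −6 dB
stop-band width comes out near 0.47 octave rather than exactly 0.50: the
raised-cosine transition places the −6 dB point ≈ 0.007 octave inside each
nominal boundary and Welch analysis smears another ≈ 0.01. Both effects
are properties of the measurement and the deliberate transition, not of
the removed band, whose interior floor is below −89 dB. The edge-band
interiors measure +20.0 dB.

## Equalization

The design intent is that spectral power below and above the notch be
comparable, so the lateral inhibitory drive is symmetric; music normally
carries much less energy in the high octaves. The algorithm
(`equalize()`, parameters in `eq_spec()`):

1. estimate the long-term average spectrum (LTAS) in 1/3-octave bands over
   100 Hz–16 kHz from Welch-averaged periodograms. Band level is reported
   as dB of **mean power per Hz** in the band, so white noise measures
   flat; the per-band energy reading is `level + 10·log10(bandwidth)`;
2. set each band's gain toward the energy-weighted mean band level,
   clamped to ±24 dB so near-empty bands are not amplified into noise;
3. interpolate the band gains linearly in log frequency, roll off to 0 dB
   over one analysis bandwidth outside the range, and apply the resulting
   static curve in one STFT pass — one gain curve per track, not a
   time-varying compressor;
4. rescale the output to the input RMS (`preserve_energy`), keeping
   loudness roughly unchanged (conserved to well under 1 %).

On the package's −3 dB/octave music surrogate the equalized LTAS is flat
within ±1 dB; the contract tested is ±3 dB.

## The placebo filter

The placebo applies a notch of the **same bandwidth** whose center jumps
`step_oct` = 1/18 octave every `dwell_s` = 5 s, continuing in one
direction until the notch band edge would cross a border, where it
reverses (reflect-before-move: the step that would cross is replaced by a
step the other way, so the band provably never leaves the borders). Three
points were genuinely open and are decided as follows:

* **Chain parity.** The placebo receives the same equalization and the
  same edge enhancement, moving with its notch. Making the two conditions
  identical except for notch-center dynamics is the configuration that
  best supports double-blinding, and nothing in the design ties edge
  enhancement to the fixed notch only.
* **Borders.** The notch band is confined to 1–16 kHz, matching the
  pitch-matching range; the initial center is drawn uniformly in log
  frequency within the admissible range.
* **Jump timing.** Jumps are quantized to STFT frame hops (23.2 ms at
  44.1 kHz); the 75 % overlap-add inherently crossfades the old and new
  masks across one window, so jumps are click-free without extra
  machinery. A 60 s run shows inter-jump intervals of 5 s ± one hop and
  step magnitudes of exactly 1/18 octave (`trace_jumps()`).

## Pitch matching

The recursive two-interval forced-choice procedure searches 1–16 kHz.
"Equally large" subintervals are read logarithmically — consistent with
Cent-domain averaging and with auditory frequency resolution — so
bisection (`bisect_interval()`) splits at the geometric mean and midpoints
are geometric means throughout. Each round asks, for the low and the high
subinterval, whether the tinnitus is more like the lower or the higher
end; the four response patterns recurse into the low subinterval, the
high subinterval, or the middle interval bounded by the two subinterval
midpoints. Two rules are not fixed by the procedure's description and are
set here:

* **Termination**: stop when the interval is ≤ 1/12 octave wide (a
  semitone, comparable to pitch-matching reliability) or after 12 rounds;
  the estimate is the final interval's geometric midpoint. From the
  4-octave range each round halves the width, so termination occurs after
  6 rounds at width 1/16 octave.
* **Inconsistent pattern** (low end of the low subinterval but high end of
  the high subinterval): the round is repeated once; if still
  inconsistent, the middle interval is taken — the pattern indicates a
  centrally located pitch.

The octave-confusion check is run downward only (matched vs matched/2),
the direction in which confusions occur in practice. Ten sessions
aggregate on the Cent scale (reference 1000 Hz, which cancels in every Hz
result): the final frequency is the Cent mean (geometric mean in Hz) and
the per-participant SD of the ten matches is the pitch-variability
covariate.

Simulated listeners (`sim_listener()`) judge each trial by comparing the
two tones against their true pitch perturbed by Gaussian noise on the
Cent scale, with a lapse probability of answering at random. With 50-cent
noise, 2 % lapses and ten sessions — plausible values for a reliable
tonal-tinnitus matcher — the median recovery error over 200 simulated
participants is well under 100 cents, and a noiseless listener reproduces
an exhaustive log-closest grid search within one terminal interval.

## Trial design arithmetic

Stratification uses age (<51 / ≥51 years) and hearing loss (<40 / ≥40 dB)
with boundary values in the upper classes, giving four strata; each
stratum gets an independent permuted-block sequence with block size 4 and
1:1 allocation, so any completed block is 2:2 and any prefix differs by
at most 2. Uniformity over the six balanced block arrangements is tested
by χ² on 10,000 blocks.

The a-priori sample size targets the Session × Group interaction with
effect size f = 0.25, α = .05, power .90, two groups, two measurements,
repeated-measures correlation ρ = 0 (conservative) and sphericity ε = 1.
Power is computed from the noncentral F distribution with
df₁ = (k−1)(m−1)ε, df₂ = (N−k)(m−1)ε and noncentrality
λ = N·f²·m/(1−ρ)·ε — the repeated-measures within-between-interaction
convention of the standard power tools, adopted because it is the one
that reproduces the planned N exactly: the smallest balanced N with power
≥ .90 is 88 (power .9065; 86 gives .8999). An independent Monte-Carlo
check simulates raw correlated pre/post data and evaluates the
interaction F through its exact identity with the squared pooled t on
change scores (itself verified against `aov()` in the unit suite); at
N = 88 the simulated power agrees with the analytic value within ±0.02
over 5000 replicates.

## Outcomes

* `vas_total()` is the arithmetic mean of the four VAS subscales
  (loudness, annoyance, awareness, handicap; 0–100 each); missing
  subscales raise an error — primary arithmetic never imputes.
* `change_score()` is post − pre per participant, so improvement on a
  symptom scale is negative; participants missing either session are
  excluded from the per-protocol set and counted.
* `morris_d()` divides the between-arm difference in mean change by the
  pooled **pretest** SD, the appropriate denominator in
  pretest–posttest–control designs, and reports a Hedges-style
  small-sample correction factor alongside. The exact variant behind a
  trial's printed effect sizes is often ambiguous, so the uncorrected and
  corrected values are both exposed and neither is used as a reproduction
  target.
* `mcid_flag()` compares |change| with the instrument's minimal clinically
  important difference: TQ 5, THQ 21, THI 7 points at ≥ (the cited
  thresholds are point values), and VAS strictly > 10 (the VAS criterion
  is worded as "greater than"). A 6.22-point VAS loudness change is
  therefore below the MCID.
* `harms_table()` counts category reports per arm with percentages of
  questionnaire respondents at one decimal, computed at full precision
  (27 of 92 respondents → 29.3 %).
* `interim_stop_check()` is a deliberate proxy: the full interim rule is a
  mixed-model interaction, but with two sessions that interaction is
  equivalent to a between-arm comparison of change scores, implemented as
  a Welch test gated on the harmful direction (treatment worsening).

## Synthetic data

The generators define the conditions under which everything above is
exercised; they emulate structure, not individual patients.

* `make_music()`: colored noise tilted −3 dB/octave (per-Hz LTAS slope)
  plus eight amplitude-modulated three-partial tone complexes — the
  salient features for this pipeline being realistic spectral imbalance
  across octaves and tonal peaks, not musical plausibility.
* `make_probe()`: flat Gaussian noise (the measurement workhorse), an
  impulse train, and an exponential chirp.
* `make_cohort()`: rosters matching the study population (age
  ~N(47.5, 10.8²) truncated to 18–70; hearing loss uniform 0–70 dB;
  pitch log-normal around 5.4 kHz truncated to 1–12 kHz), eligible by
  construction; outcome tables over baseline/pre/post/follow-up with arm
  effects injected as mean change scores (SD 10 points of change noise, a
  realistic value for VAS change variability) so recovery via
  `change_score()` is exactly checkable; 17 % dropout marked as missing
  after pre; per-category harm flags.

What passing these simulations shows is that the procedures are
implemented correctly under their stated models. It does not show that
real listeners behave like the noise-plus-lapse model, that real music
resembles tilted noise, or that real VAS changes are Gaussian — those are
exactly the things a trial measures.

## Numerical choices and limitations

* Problem sizes: geometry on 10–30 s probes, placebo traces of 60 s,
  200-listener recovery, 5000-replicate Monte-Carlo power, 10,000-block
  uniformity — sizes at which every sampling check has comfortable margin
  against its tolerance.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; identical inputs and seeds reproduce outputs
  bit-identically (WAV float32).
* Degenerate inputs: silent audio yields floor-valued, flagged LTAS;
  zero-power bins report gain at a −120 dB floor; walks whose borders
  cannot contain the notch plus two steps are rejected at construction;
  ties in forced choices resolve to the lower end deterministically.
* The STFT gain model is linear and time-invariant within a frame: no
  perceptual loudness model, no dynamics processing, no real-time
  constraints — the package targets analysis and verification, not
  deployment on playback hardware.
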