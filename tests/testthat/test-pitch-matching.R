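test_that("cent conversion is exact and invertible", {
  expect_equal(hz_to_cents(1000, 1000), 0)
  expect_equal(hz_to_cents(2000, 1000), 1200)
  f <- c(1000, 1234.5, 5406, 15999)
  expect_equal(cents_to_hz(hz_to_cents(f)), f, tolerance = 1e-9)
  expect_error(hz_to_cents(-1), "f > 0")
})

test_that("bisection splits at the geometric mean, halving octave width", {
  iv <- freq_interval(1000, 16000)
  subs <- bisect_interval(iv)
  expect_equal(subs$low$high_hz, 4000) # sqrt(1000 * 16000)
  expect_equal(bisect_interval(freq_interval(2000, 8000))$low$high_hz, 4000)
  expect_equal(interval_width_oct(subs$low), interval_width_oct(iv) / 2)
  expect_equal(interval_width_oct(subs$high), interval_width_oct(iv) / 2)
})

test_that("the four choice patterns map to the documented intervals", {
  iv <- freq_interval(1000, 16000)
  low <- next_interval("low_end", "low_end", iv)
  expect_equal(c(low$interval$low_hz, low$interval$high_hz), c(1000, 4000))
  high <- next_interval("high_end", "high_end", iv)
  expect_equal(c(high$interval$low_hz, high$interval$high_hz), c(4000, 16000))
  mid <- next_interval("high_end", "low_end", iv)
  expect_equal(c(mid$interval$low_hz, mid$interval$high_hz), c(2000, 8000))
  expect_equal(mid$pattern, "middle")
  inc <- next_interval("low_end", "high_end", iv)
  expect_equal(inc$pattern, "inconsistent")
  expect_equal(c(inc$interval$low_hz, inc$interval$high_hz), c(2000, 8000))
})

test_that("a noiseless session matches the brute-force log-closest search", {
  cfg <- match_config()
  for (true_hz in c(1050, 1500, 2718, 5406, 8000, 11500)) {
    s <- run_session(sim_listener(true_hz, 0, 0), cfg, seed = 1)
    oracle <- brute_force_match(true_hz)
    terminal_oct <- interval_width_oct(freq_interval(1000, 16000)) /
      2^s$rounds_used
    expect_lt(abs(log2(s$matched_hz / oracle)), terminal_oct + 1e-9)
  }
})

test_that("sessions respect range bounds, nesting and determinism", {
  s <- run_session(sim_listener(1000, 0, 0), seed = 2)
  expect_gte(s$matched_hz, 1000)
  expect_lt(abs(log2(s$matched_hz / 1000)), 1 / 12)
  # interval nesting: widths never increase, each interval inside parent
  noisy <- sim_listener(3000, 200, 0.1)
  s2 <- run_session(noisy, seed = 5)
  r <- s2$responses
  expect_true(all(diff(log2(r$high_hz / r$low_hz)) <= 1e-12))
  expect_true(all(diff(r$low_hz) >= -1e-9))
  expect_true(all(diff(r$high_hz) <= 1e-9))
  s3 <- run_session(noisy, seed = 5)
  expect_identical(s2$responses, s3$responses)
  expect_identical(s2$matched_hz, s3$matched_hz)
})

test_that("octave confusion keeps the alternative closer to the true pitch", {
  hears_lower <- sim_listener(2000, 0, 0)
  expect_equal(octave_confusion(hears_lower, 4000), 2000)
  hears_matched <- sim_listener(4000, 0, 0)
  expect_equal(octave_confusion(hears_matched, 4000), 4000)
  # skipped when the lower octave is not presentable
  expect_equal(octave_confusion(hears_lower, 30, min_hz = 20), 30)
  expect_error(sim_listener(4000, lapse_rate = 0.5), "lapse_rate")
})

test_that("aggregation averages on the Cent scale (geometric mean in Hz)", {
  est <- aggregate_sessions(rep(5000, 10))
  expect_equal(est$mean_hz, 5000)
  expect_equal(est$sd_cents, 0)
  expect_equal(est$n_sessions, 10)
  est2 <- aggregate_sessions(c(1000, 4000))
  expect_equal(est2$mean_hz, 2000) # geometric, not arithmetic, mean
  # the cents reference cancels in the Hz result
  est3 <- aggregate_sessions(c(1000, 4000), cents_ref = 440)
  expect_equal(est3$mean_hz, est2$mean_hz)
  expect_error(aggregate_sessions(numeric(0)), "at least one")
})

test_that("ten sessions over five days aggregate to n_sessions = 10", {
  li <- sim_listener(5406, 50, 0.02)
  sessions <- lapply(1:10, function(i) run_session(li, seed = 100 + i))
  est <- aggregate_sessions(sessions)
  expect_equal(est$n_sessions, 10L)
  expect_lt(abs(est$mean_cents - hz_to_cents(5406)), 150)
})

test_that("recovery error shrinks as judgment noise vanishes", {
  true_hz <- 2^seq(log2(1200), log2(11000), length.out = 15)
  err_at_noise <- vapply(c(200, 50, 0), function(noise) {
    errs <- vapply(seq_along(true_hz), function(p) {
      li <- sim_listener(true_hz[p], noise, 0)
      est <- aggregate_sessions(
        lapply(1:10, function(i) run_session(li, seed = 1000 * p + 10 * noise + i))
      )
      abs(est$mean_cents - hz_to_cents(true_hz[p]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(err_at_noise) <= 1e-9))
})
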