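# Shared fixtures, memoized so expensive audio processing runs once per
# test session. Everything is generated in code from fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

probe_10s <- function() {
  fixture("probe_10s", function() {
    make_probe("flat_noise", duration_s = 10, seed = 101)
  })
}

target_4k <- function() {
  fixture("target_4k", function() process_target(probe_10s(), 4000))
}

resp_4k <- function() {
  fixture("resp_4k", function() measure_response(probe_10s(), target_4k()))
}

geometry_4k <- function() {
  fixture("geometry_4k", function() {
    measure_notch_geometry(resp_4k(), notch_spec(4000))
  })
}

music_10s <- function() {
  fixture("music_10s", function() {
    make_music(music_model(duration_s = 10), seed = 103)
  })
}

# independent oracle for the matching procedure: exhaustive search over a
# dense log-frequency grid for the candidate closest to the true pitch
brute_force_match <- function(true_hz, range_hz = c(1000, 16000),
                              grid_oct = 1 / 400) {
  grid <- 2^seq(log2(range_hz[1]), log2(range_hz[2]), by = grid_oct)
  grid[which.min(abs(log2(grid / true_hz)))]
}

# a small deterministic long outcome table: two arms, complete pre/post
make_outcome_fixture <- function(n_per_arm = 5, pre_t = 50, post_t = 44,
                                 pre_c = 50, post_c = 50,
                                 measure = "vas_loudness") {
  ids_t <- sprintf("T%02d", seq_len(n_per_arm))
  ids_c <- sprintf("C%02d", seq_len(n_per_arm))
  # zero-mean jitter, different at pre and post so change scores vary
  jit_pre <- seq(-2, 2, length.out = n_per_arm)
  jit_post <- -jit_pre
  rbind(
    data.frame(id = ids_t, arm = "treatment", session = "pre",
               measure = measure, value = pre_t + jit_pre),
    data.frame(id = ids_t, arm = "treatment", session = "post",
               measure = measure, value = post_t + jit_post),
    data.frame(id = ids_c, arm = "placebo", session = "pre",
               measure = measure, value = pre_c + jit_pre),
    data.frame(id = ids_c, arm = "placebo", session = "post",
               measure = measure, value = post_c + jit_post)
  )
}
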