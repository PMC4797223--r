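eligible_p <- function(...) {
  utils::modifyList(
    list(
      age = 47, tinnitus_hz = 5406, hearing_loss_db = 41,
      chronicity_months = 84, mental_disorder = FALSE,
      otological_disease = FALSE, substance_use = FALSE,
      concurrent_therapy = FALSE, consent = TRUE
    ),
    list(...)
  )
}

test_that("screening applies every inclusion criterion with reasons", {
  ok <- screen_participant(eligible_p())
  expect_true(ok$eligible)
  expect_length(ok$reasons, 0)
  expect_equal(screen_participant(eligible_p(tinnitus_hz = 13000))$reasons,
               "pitch")
  expect_equal(screen_participant(eligible_p(age = 72))$reasons, "age")
  expect_equal(screen_participant(eligible_p(hearing_loss_db = 71))$reasons,
               "hearing_loss")
  expect_equal(screen_participant(eligible_p(chronicity_months = 2))$reasons,
               "chronicity")
  multi <- screen_participant(eligible_p(age = 17, consent = FALSE,
                                         mental_disorder = TRUE))
  expect_setequal(multi$reasons, c("age", "mental_disorder", "consent"))
  expect_error(screen_participant(list(age = 50)), "missing field")
})

test_that("stratification yields four strata with >= boundary convention", {
  expect_equal(as.character(stratify(51, 40)), "at_least_51.at_least_40")
  expect_equal(as.character(stratify(50.9, 39.9)), "under51.under40")
  expect_equal(as.character(stratify(21, 0)), "under51.under40")
  grid <- expand.grid(age = c(20, 50, 51, 70), hl = c(0, 39, 40, 70))
  expect_equal(nlevels(stratify(grid$age, grid$hl)), 4L)
  expect_setequal(as.character(unique(stratify(grid$age, grid$hl))),
                  levels(stratify(1, 1)))
})

test_that("permuted blocks balance arms within every stratum", {
  roster <- data.frame(
    id = sprintf("p%02d", 1:24),
    age = rep(c(30, 60), each = 12),
    hearing_loss_db = rep(c(10, 50, 10, 50), each = 6)
  )
  alloc <- randomize_blocks(roster, seed = 42)
  expect_equal(nrow(alloc), 24L)
  for (s in unique(alloc$stratum)) {
    sub <- alloc[alloc$stratum == s, ]
    for (b in unique(sub$block_index)) {
      block <- sub[sub$block_index == b, ]
      if (nrow(block) == 4L) {
        expect_equal(sum(block$arm == "treatment"), 2L)
      }
    }
  }
  # any prefix differs by at most 2; prefixes of complete blocks by 0
  for (s in unique(alloc$stratum)) {
    arms <- alloc$arm[alloc$stratum == s]
    running <- cumsum(arms == "treatment") - cumsum(arms == "placebo")
    expect_true(all(abs(running) <= 2))
    full <- seq_along(arms) %% 4 == 0
    expect_true(all(running[full] == 0))
  }
  expect_identical(randomize_blocks(roster, seed = 42), alloc)
  expect_error(randomize_blocks(roster, block_size = 3), "even")
})

test_that("all six block arrangements occur uniformly", {
  roster <- data.frame(id = seq_len(4 * 2000), age = 30, hearing_loss_db = 10)
  alloc <- randomize_blocks(roster, seed = 99)
  pattern <- tapply(alloc$arm, alloc$block_index,
                    function(a) paste(substr(a, 1, 1), collapse = ""))
  tab <- table(pattern)
  expect_equal(length(tab), 6L)
  expect_true(all(abs(tab / 2000 - 1 / 6) < 0.04))
})

test_that("the interaction power routine reproduces the planned N = 88", {
  cfg <- power_config() # f = .25, alpha = .05, power = .90, 2x2, rho = 0
  expect_equal(sample_size_rm_interaction(cfg), 88L)
  # minimality: one group-multiple less misses the target
  expect_lt(power_at(cfg, 86), 0.90)
  expect_gte(power_at(cfg, 88), 0.90)
})

test_that("power responds to its parameters as the noncentral F dictates", {
  cfg <- power_config()
  n80 <- sample_size_rm_interaction(power_config(target_power = 0.80))
  expect_lt(n80, 88)
  n_corr <- sample_size_rm_interaction(power_config(rho = 0.5))
  expect_lt(n_corr, 88)
  expect_equal(power_at(power_config(effect_f = 1e-9), 88), 0.05,
               tolerance = 1e-4) # null effect: power = alpha
  sweep <- vapply(seq(4, 400, by = 2), function(N) power_at(cfg, N),
                  numeric(1))
  expect_true(all(diff(sweep) > 0)) # strictly increasing in N
  expect_error(sample_size_rm_interaction(power_config(effect_f = 1e-6),
                                          max_n = 500),
               "not reachable")
})

test_that("the difference-score identity matches the mixed-ANOVA F", {
  set.seed(13)
  n <- 8
  dat <- data.frame(
    id = factor(rep(1:(2 * n), each = 2)),
    group = factor(rep(c("t", "c"), each = 2 * n)),
    session = factor(rep(c("pre", "post"), 2 * n)),
    y = rnorm(4 * n)
  )
  fit <- stats::aov(y ~ group * session + Error(id / session), data = dat)
  f_aov <- summary(fit)[["Error: id:session"]][[1]]["group:session",
                                                   "F value"]
  d <- with(dat, y[session == "post"] - y[session == "pre"])
  g <- dat$group[dat$session == "pre"]
  tt <- stats::t.test(d[g == "t"], d[g == "c"], var.equal = TRUE)
  expect_equal(unname(tt$statistic)^2, f_aov, tolerance = 1e-8)
})

test_that("Monte-Carlo power agrees with the analytic noncentral F", {
  cfg <- power_config()
  p_mc <- mc_power_interaction(cfg, 88, n_rep = 2000, seed = 17)
  expect_equal(p_mc, power_at(cfg, 88), tolerance = 0.03)
})
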