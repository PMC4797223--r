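test_that("VAS total is the mean of the four subscales", {
  expect_equal(round(vas_total(50.70, 39.70, 52.32, 28.58), 2), 42.83)
  expect_equal(round(vas_total(48.86, 40.32, 58.30, 31.36), 2), 44.71)
  expect_equal(vas_total(0, 0, 0, 0), 0)
  # permutation invariance and bounds
  expect_equal(vas_total(28.58, 52.32, 39.70, 50.70),
               vas_total(50.70, 39.70, 52.32, 28.58))
  expect_error(vas_total(50, NA, 30, 20), "no imputation")
  expect_error(vas_total(50, 120, 30, 20), "\\[0, 100\\]")
  expect_error(vas_total(list(vas_loudness = 50)), "missing VAS subscale")
  rec <- list(vas_loudness = 50.70, vas_annoyance = 39.70,
              vas_awareness = 52.32, vas_handicap = 28.58)
  expect_equal(round(vas_total(rec), 2), 42.83)
})

test_that("change scores use post minus pre and exclude incomplete pairs", {
  records <- make_outcome_fixture(pre_t = 53.46, post_t = 47.24,
                                  pre_c = 46.15, post_c = 47.00)
  ch <- change_score(records, "vas_loudness")
  mean_t <- mean(ch$change[ch$arm == "treatment"])
  expect_equal(-mean_t, 6.22, tolerance = 1e-9) # pre-minus-post improvement
  expect_lt(mean_t, 0) # improvement is a negative post-pre change
  expect_equal(attr(ch, "n_excluded"), 0L)
  # dropping one post value excludes exactly that participant
  records$value[records$id == "T01" & records$session == "post"] <- NA
  ch2 <- change_score(records, "vas_loudness")
  expect_equal(nrow(ch2), 9L)
  expect_equal(attr(ch2, "n_excluded"), 1L)
  same <- change_score(make_outcome_fixture(pre_t = 40, post_t = 40),
                       "vas_loudness")
  expect_equal(mean(same$change[same$arm == "treatment"]), 0)
})

test_that("Morris d follows the pooled-pretest-SD formula", {
  res <- morris_d(-5, 0, 10, 10, 50, 50)
  expect_equal(res$d, -0.5)
  expect_equal(res$correction, 1 - 3 / (4 * 98 - 1))
  expect_equal(res$d_corrected, -0.5 * res$correction)
  expect_equal(morris_d(-5, -5, 10, 10, 50, 50)$d, 0)
  expect_equal(morris_d(-5, 0, 20, 20, 50, 50)$d, -0.25) # scale property
  expect_error(morris_d(-5, 0, 0, 0, 50, 50), "zero")
})

test_that("Morris d from summaries equals a brute-force raw-data version", {
  set.seed(31)
  pre_t <- rnorm(40, 50, 20); post_t <- pre_t + rnorm(40, -6, 10)
  pre_c <- rnorm(43, 50, 20); post_c <- pre_c + rnorm(43, 0, 10)
  via_summaries <- morris_d(
    mean(post_t - pre_t), mean(post_c - pre_c),
    sd(pre_t), sd(pre_c), 40, 43
  )$d
  brute <- (mean(post_t - pre_t) - mean(post_c - pre_c)) /
    sqrt((39 * var(pre_t) + 42 * var(pre_c)) / 81)
  expect_equal(via_summaries, brute, tolerance = 1e-12)
})

test_that("MCID flags use strict > for VAS and >= for questionnaires", {
  expect_false(mcid_flag(6.22, "vas_loudness")) # not clinically relevant
  expect_false(mcid_flag(10, "vas")) # strictly greater than 10
  expect_true(mcid_flag(10.01, "vas"))
  expect_true(mcid_flag(5, "tq")) # questionnaire thresholds met at equality
  expect_true(mcid_flag(21, "thq"))
  expect_true(mcid_flag(-7, "thi")) # magnitude rule
  expect_false(mcid_flag(6.9, "thi"))
  expect_error(mcid_flag(5, "cgi"), "unknown measure")
})

test_that("planned dose multiplies out to 168 hours", {
  expect_equal(planned_dose(), 168)
  expect_equal(planned_dose(1, 7, 12), 84)
  expect_equal(planned_dose(2, 7, 0), 0)
})

test_that("harms tabulation counts per arm and percentages of respondents", {
  harms <- rbind(
    data.frame(id = sprintf("t%d", 1:5), arm = "treatment",
               category = "consistently_louder"),
    data.frame(id = sprintf("p%d", 1:5), arm = "placebo",
               category = "consistently_louder"),
    data.frame(id = c(sprintf("t%d", 6:12), sprintf("p%d", 6:15)),
               arm = rep(c("treatment", "placebo"), c(7, 10)),
               category = "additional_sound")
  )
  tab <- harms_table(harms, respondents = 92)
  any_row <- tab[tab$category == "any_harm", ]
  expect_equal(any_row$total, 27)
  expect_equal(any_row$pct_of_respondents, round(100 * 27 / 92, 1)) # 29.3
  cl <- tab[tab$category == "consistently_louder", ]
  expect_equal(cl$total, 10)
  expect_equal(cl$pct_of_respondents, 10.9)
  expect_equal(any_row$treatment, 12)
  expect_equal(any_row$placebo, 15)
  # row/column consistency: per-arm counts sum to totals
  expect_equal(tab$treatment + tab$placebo, tab$total)
  # exclusive categories sum to at most the any-harm count
  expect_lte(sum(tab$total[tab$category != "any_harm"]), any_row$total + 1)
  empty <- harms_table(
    data.frame(id = character(), arm = character(), category = character()),
    respondents = 92
  )
  expect_equal(empty$total, 0L)
  expect_equal(empty$pct_of_respondents, 0)
  expect_error(harms_table(harms, 0), "positive")
})

test_that("interim check stops only on significant harm to the treatment arm", {
  same <- make_outcome_fixture(pre_t = 50, post_t = 50, pre_c = 50,
                               post_c = 50, n_per_arm = 20)
  expect_false(interim_stop_check(same, "vas_loudness")$stop)
  worse <- make_outcome_fixture(pre_t = 50, post_t = 70, pre_c = 50,
                                post_c = 50, n_per_arm = 20)
  res <- interim_stop_check(worse, "vas_loudness")
  expect_true(res$stop)
  expect_lt(res$p, 0.05)
  better <- make_outcome_fixture(pre_t = 50, post_t = 30, pre_c = 50,
                                 post_c = 50, n_per_arm = 20)
  res_b <- interim_stop_check(better, "vas_loudness")
  expect_false(res_b$stop) # direction gate: benefit never stops the trial
  expect_lt(res_b$p, 0.05)
  tiny <- make_outcome_fixture(n_per_arm = 1)
  expect_error(interim_stop_check(tiny, "vas_loudness"), "two participants")
})

test_that("analysis sets separate intention-to-treat from per-protocol", {
  records <- make_outcome_fixture(n_per_arm = 50)
  drop_ids <- c(sprintf("T%02d", 1:9), sprintf("C%02d", 1:8))
  records$value[records$id %in% drop_ids & records$session == "post"] <- NA
  sets <- analysis_sets(records, "vas_loudness")
  expect_equal(sets$n_itt, 100L)
  expect_equal(sets$n_per_protocol, 83L) # 100 enrolled minus 17 dropouts
  expect_equal(sets$n_dropped, 17L)
})
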