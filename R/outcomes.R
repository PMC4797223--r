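# Outcome arithmetic: VAS composite, change scores, Morris effect size,
# MCID flags, dose, harms tabulation, interim stopping proxy. Outcome
# tables are long data.frames: id, arm, session, measure, value, with
# session one of baseline/pre/post/followup.

outcome_sessions <- c("baseline", "pre", "post", "followup")
vas_subscales <- c("vas_loudness", "vas_annoyance", "vas_awareness",
                   "vas_handicap")

#' VAS total score
#'
#' The composite primary outcome: the arithmetic mean of the four visual
#' analog subscales (loudness, annoyance, awareness, handicap), each rated
#' 0-100. Missing subscales raise an error rather than being imputed.
#'
#' @param loudness,annoyance,awareness,handicap Subscale values, 0-100.
#'   Alternatively pass a single named list/vector containing the four
#'   `vas_*` fields as `loudness`.
#' @return The mean of the four subscales.
#' @examples
#' vas_total(50.70, 39.70, 52.32, 28.58) # 42.83: treatment baseline mean
#' @export
vas_total <- function(loudness, annoyance, awareness, handicap) {
  if (missing(annoyance) && (is.list(loudness) || length(loudness) > 1L)) {
    rec <- loudness
    miss <- setdiff(vas_subscales, names(rec))
    if (length(miss) > 0L) {
      stop("missing VAS subscale(s): ", paste(miss, collapse = ", "))
    }
    loudness <- rec[["vas_loudness"]]
    annoyance <- rec[["vas_annoyance"]]
    awareness <- rec[["vas_awareness"]]
    handicap <- rec[["vas_handicap"]]
  }
  vals <- cbind(loudness, annoyance, awareness, handicap)
  if (anyNA(vals)) stop("missing VAS subscale value; no imputation is done")
  if (any(vals < 0 | vals > 100)) stop("VAS values must lie in [0, 100]")
  rowMeans(vals)
}

check_outcomes <- function(records) {
  need <- c("id", "arm", "session", "measure", "value")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("outcome table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !records$session %in% outcome_sessions
  if (any(bad)) {
    stop("unknown session label(s): ",
         paste(unique(records$session[bad]), collapse = ", "))
  }
  records
}

#' Per-participant change scores
#'
#' Computes `value(to_session) - value(from_session)` per participant for
#' one measure. Participants missing either session are excluded from the
#' per-protocol result; their count is attached as attribute
#' `n_excluded`.
#'
#' @param records Long outcome table (`id`, `arm`, `session`, `measure`,
#'   `value`).
#' @param measure Measure name, e.g. `"vas_loudness"`.
#' @param from_session,to_session Session labels (default pre -> post).
#' @return Data frame `id`, `arm`, `change`, with attribute `n_excluded`.
#' @export
change_score <- function(records, measure, from_session = "pre",
                         to_session = "post") {
  records <- check_outcomes(records)
  sub <- records[records$measure == measure & !is.na(records$value), ]
  from <- sub[sub$session == from_session, c("id", "arm", "value")]
  to <- sub[sub$session == to_session, c("id", "value")]
  merged <- merge(from, to, by = "id", suffixes = c("_from", "_to"))
  out <- data.frame(
    id = merged$id, arm = merged$arm,
    change = merged$value_to - merged$value_from
  )
  ids_any <- unique(sub$id)
  attr(out, "n_excluded") <- length(setdiff(ids_any, out$id))
  out
}

#' Morris pretest-pooled effect size
#'
#' Effect size for pretest-posttest-control designs: the difference in
#' mean change between arms divided by the pooled pretest SD,
#' `d = (mean_change_t - mean_change_c) / sd_pre_pooled`. A Hedges-style
#' small-sample correction `1 - 3 / (4 (n_t + n_c - 2) - 1)` is reported
#' alongside the uncorrected value.
#'
#' @param mean_change_t,mean_change_c Mean change score per arm.
#' @param sd_pre_t,sd_pre_c Pretest SD per arm.
#' @param n_t,n_c Arm sizes (each >= 2).
#' @return List: `d`, `d_corrected`, `correction`, `sd_pre_pooled`.
#' @export
morris_d <- function(mean_change_t, mean_change_c, sd_pre_t, sd_pre_c,
                     n_t, n_c) {
  stopifnot(n_t >= 2, n_c >= 2, sd_pre_t >= 0, sd_pre_c >= 0)
  sd_pooled <- sqrt(((n_t - 1) * sd_pre_t^2 + (n_c - 1) * sd_pre_c^2) /
                      (n_t + n_c - 2))
  if (sd_pooled == 0) stop("pooled pretest SD is zero")
  d <- (mean_change_t - mean_change_c) / sd_pooled
  j <- 1 - 3 / (4 * (n_t + n_c - 2) - 1)
  list(d = d, d_corrected = j * d, correction = j, sd_pre_pooled = sd_pooled)
}

#' Minimal clinically important difference thresholds
#'
#' Published MCIDs for the trial's instruments: 5 score points for the TQ,
#' 21 for the THQ, 7 for the THI and 10 for a VAS.
#'
#' @param tq,thq,thi,vas Threshold overrides (score points).
#' @return Named list of thresholds.
#' @export
mcid_table <- function(tq = 5, thq = 21, thi = 7, vas = 10) {
  stopifnot(tq > 0, thq > 0, thi > 0, vas > 0)
  list(tq = tq, thq = thq, thi = thi, vas = vas)
}

#' Flag a change score against its MCID
#'
#' Compares `|change|` with the measure's threshold. VAS changes must be
#' strictly greater than 10 points to count as clinically relevant; the
#' questionnaire thresholds (TQ/THQ/THI) are met at equality.
#'
#' @param change Observed change score.
#' @param measure One of `"tq"`, `"thq"`, `"thi"`, `"vas"` (any `vas_*`
#'   label maps to `"vas"`).
#' @param table An [mcid_table()].
#' @return Logical: is the change clinically relevant?
#' @examples
#' mcid_flag(6.22, "vas") # FALSE: below the 10-point VAS MCID
#' @export
mcid_flag <- function(change, measure, table = mcid_table()) {
  key <- tolower(measure)
  if (startsWith(key, "vas")) key <- "vas"
  if (!key %in% names(table)) stop("unknown measure: ", measure)
  thr <- table[[key]]
  if (key == "vas") abs(change) > thr else abs(change) >= thr
}

#' Planned training dose
#'
#' Total listening hours of the protocol: two successive hours per day,
#' every day, for twelve weeks gives 168 h.
#'
#' @param hours_per_day,days_per_week,weeks Schedule components.
#' @return Total hours.
#' @export
planned_dose <- function(hours_per_day = 2, days_per_week = 7, weeks = 12) {
  stopifnot(hours_per_day >= 0, days_per_week >= 0, weeks >= 0)
  hours_per_day * days_per_week * weeks
}

#' Tabulate reported harms
#'
#' Per-category counts by arm with totals, plus the "any harm" row
#' (participants reporting at least one category) and percentages of
#' questionnaire respondents, rounded to one decimal place.
#'
#' @param harms Data frame `id`, `arm`, `category` (one row per reported
#'   harm).
#' @param respondents Number of participants who answered the harms
#'   questionnaire (the percentage denominator).
#' @return Data frame `category`, `treatment`, `placebo`, `total`,
#'   `pct_of_respondents`, with the `any_harm` summary as the first row.
#' @export
harms_table <- function(harms, respondents) {
  stopifnot(all(c("id", "arm", "category") %in% names(harms)))
  if (respondents <= 0) stop("respondents must be positive")
  arms <- c("treatment", "placebo")
  count_arm <- function(df, a) length(unique(df$id[df$arm == a]))
  cats <- unique(harms$category)
  rows <- lapply(cats, function(cat) {
    sub <- harms[harms$category == cat, ]
    tr <- count_arm(sub, "treatment")
    pl <- count_arm(sub, "placebo")
    data.frame(
      category = cat, treatment = tr, placebo = pl, total = tr + pl
    )
  })
  any_tr <- count_arm(harms, "treatment")
  any_pl <- count_arm(harms, "placebo")
  out <- rbind(
    data.frame(
      category = "any_harm", treatment = any_tr, placebo = any_pl,
      total = any_tr + any_pl
    ),
    do.call(rbind, rows)
  )
  if (is.null(out)) {
    out <- data.frame(
      category = "any_harm", treatment = 0L, placebo = 0L, total = 0L
    )
  }
  out$pct_of_respondents <- round(100 * out$total / respondents, 1)
  out
}

#' Interim stopping check (change-score proxy)
#'
#' Proxy for the trial's interim rule that a significant Session-by-Group
#' interaction revealing a negative effect in the treatment arm stops the
#' trial: a Welch two-sample comparison of post-minus-pre changes between
#' arms, gated on the harmful direction (treatment mean change exceeding
#' placebo, i.e. worsening symptom scores).
#'
#' @param records Long outcome table.
#' @param measure Primary outcome measure to test.
#' @param alpha Significance level (default .05).
#' @return List: `stop` (logical), `statistic` (Welch t), `p`
#'   (two-sided), `mean_change_treatment`, `mean_change_placebo`.
#' @export
interim_stop_check <- function(records, measure, alpha = 0.05) {
  ch <- change_score(records, measure)
  x <- ch$change[ch$arm == "treatment"]
  y <- ch$change[ch$arm == "placebo"]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least two participants per arm with both sessions")
  }
  tt <- stats::t.test(x, y) # Welch by default
  harmful <- mean(x) > mean(y) # higher symptom change = worse
  list(
    stop = tt$p.value < alpha && harmful,
    statistic = unname(tt$statistic), p = tt$p.value,
    mean_change_treatment = mean(x), mean_change_placebo = mean(y)
  )
}

#' Analysis-set sizes
#'
#' Intention-to-treat vs per-protocol participant counts from an outcome
#' table: ITT counts everyone with any record; per-protocol counts those
#' with non-missing values in both contrast sessions for the given
#' measure.
#'
#' @param records Long outcome table.
#' @param measure Measure defining completeness.
#' @param from_session,to_session Contrast sessions.
#' @return List: `n_itt`, `n_per_protocol`, `n_dropped`.
#' @export
analysis_sets <- function(records, measure, from_session = "pre",
                          to_session = "post") {
  records <- check_outcomes(records)
  n_itt <- length(unique(records$id))
  ch <- change_score(records, measure, from_session, to_session)
  list(
    n_itt = n_itt, n_per_protocol = nrow(ch),
    n_dropped = n_itt - nrow(ch)
  )
}
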