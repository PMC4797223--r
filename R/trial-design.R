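#' Eligibility screening
#'
#' Applies the trial's inclusion/exclusion criteria to one participant
#' record: chronic (>= 3 months) tonal tinnitus with a dominant frequency
#' between 1 and 12 kHz, no more than 70 dB HL hearing loss in the
#' half-octave range around the tinnitus frequency, age 18-70, and none of
#' the exclusion flags (mental/neurological disorder, acute otological
#' disease, substance use, concurrent therapy) set, with written consent.
#'
#' @param p Named list or one-row data.frame with fields `age`,
#'   `tinnitus_hz`, `hearing_loss_db`, `chronicity_months`, and logical
#'   flags `mental_disorder`, `otological_disease`, `substance_use`,
#'   `concurrent_therapy`, `consent`.
#' @return List: `eligible` (logical) and `reasons` (character vector of
#'   every failed criterion; empty when eligible).
#' @export
screen_participant <- function(p) {
  need <- c(
    "age", "tinnitus_hz", "hearing_loss_db", "chronicity_months",
    "mental_disorder", "otological_disease", "substance_use",
    "concurrent_therapy", "consent"
  )
  missing_f <- setdiff(need, names(p))
  if (length(missing_f) > 0L) {
    stop("participant record is missing field(s): ",
         paste(missing_f, collapse = ", "))
  }
  vals <- lapply(p[need], function(v) v[[1]])
  if (any(vapply(vals, function(v) is.na(v), logical(1)))) {
    stop("participant record contains missing values")
  }
  reasons <- character()
  if (vals$chronicity_months < 3) reasons <- c(reasons, "chronicity")
  if (vals$tinnitus_hz < 1000 || vals$tinnitus_hz > 12000) {
    reasons <- c(reasons, "pitch")
  }
  if (vals$hearing_loss_db > 70) reasons <- c(reasons, "hearing_loss")
  if (vals$age < 18 || vals$age > 70) reasons <- c(reasons, "age")
  if (isTRUE(vals$mental_disorder)) reasons <- c(reasons, "mental_disorder")
  if (isTRUE(vals$otological_disease)) reasons <- c(reasons, "otological_disease")
  if (isTRUE(vals$substance_use)) reasons <- c(reasons, "substance_use")
  if (isTRUE(vals$concurrent_therapy)) reasons <- c(reasons, "concurrent_therapy")
  if (!isTRUE(vals$consent)) reasons <- c(reasons, "consent")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Stratify by age and hearing loss
#'
#' The trial's two stratification factors with their boundary convention:
#' age below vs at least 51 years, and hearing loss below vs at least
#' 40 dB. Boundary values (exactly 51 y, exactly 40 dB) belong to the
#' "at least" classes. Four strata result.
#'
#' @param age Age in years (vectorized).
#' @param hearing_loss_db Maximum hearing loss in the half-octave range
#'   around the tinnitus frequency, dB.
#' @return Factor with levels `under51.under40`, `under51.at_least_40`,
#'   `at_least_51.under40`, `at_least_51.at_least_40`.
#' @export
stratify <- function(age, hearing_loss_db) {
  a <- ifelse(age >= 51, "at_least_51", "under51")
  h <- ifelse(hearing_loss_db >= 40, "at_least_40", "under40")
  factor(
    paste(a, h, sep = "."),
    levels = c(
      "under51.under40", "under51.at_least_40",
      "at_least_51.under40", "at_least_51.at_least_40"
    )
  )
}

#' Stratified permuted-block randomization
#'
#' Allocates participants 1:1 to treatment and placebo within each
#' stratum using independent permuted blocks: every complete block of
#' `block_size` contains exactly `block_size / 2` of each arm in random
#' order. Assignment follows roster order within each stratum.
#'
#' @param roster Data frame with columns `id`, `age`, `hearing_loss_db`.
#' @param block_size Even block size (default 4).
#' @param seed Integer seed; the allocation list is reproducible from it.
#' @return Data frame `id`, `stratum`, `arm`, `block_index`,
#'   `position_in_block`, in roster order.
#' @export
randomize_blocks <- function(roster, block_size = 4L, seed = NULL) {
  stopifnot(all(c("id", "age", "hearing_loss_db") %in% names(roster)))
  block_size <- as.integer(block_size)
  if (block_size < 2L || block_size %% 2L != 0L) {
    stop("block_size must be even to allow 1:1 allocation")
  }
  with_seed(seed, {
    strata <- stratify(roster$age, roster$hearing_loss_db)
    arm <- character(nrow(roster))
    block_index <- integer(nrow(roster))
    position <- integer(nrow(roster))
    for (s in levels(strata)) {
      idx <- which(strata == s)
      if (length(idx) == 0L) next
      n_blocks <- ceiling(length(idx) / block_size)
      seq_arms <- unlist(lapply(seq_len(n_blocks), function(b) {
        sample(rep(c("treatment", "placebo"), block_size / 2L))
      }))
      arm[idx] <- seq_arms[seq_along(idx)]
      block_index[idx] <- (seq_along(idx) - 1L) %/% block_size + 1L
      position[idx] <- (seq_along(idx) - 1L) %% block_size + 1L
    }
    data.frame(
      id = roster$id, stratum = strata, arm = arm,
      block_index = block_index, position_in_block = position
    )
  })
}

#' Power-analysis configuration
#'
#' Parameters of the repeated-measures within-between interaction power
#' analysis, following the G*Power 3 convention: noncentrality
#' `lambda = N * f^2 * m / (1 - rho) * epsilon` with numerator df
#' `(k-1)(m-1)*epsilon` and denominator df `(N-k)(m-1)*epsilon`.
#'
#' @param effect_f Standardized effect size f (0.25 = medium).
#' @param alpha Type-I error level.
#' @param target_power Desired power.
#' @param k Number of groups.
#' @param m Number of repeated measurements.
#' @param rho Correlation between repeated measures (0 is the conservative
#'   choice; larger values shrink the required N).
#' @param epsilon Nonsphericity correction (1 = sphericity).
#' @return A `power_config`.
#' @export
power_config <- function(effect_f = 0.25, alpha = 0.05, target_power = 0.90,
                         k = 2L, m = 2L, rho = 0, epsilon = 1) {
  stopifnot(
    effect_f > 0, alpha > 0, alpha < 1, target_power > 0, target_power < 1,
    k >= 2L, m >= 2L, rho >= 0, rho < 1, epsilon > 0, epsilon <= 1
  )
  structure(
    list(
      effect_f = effect_f, alpha = alpha, target_power = target_power,
      k = as.integer(k), m = as.integer(m), rho = rho, epsilon = epsilon
    ),
    class = "power_config"
  )
}

#' Power of the within-between interaction F test at a given N
#'
#' @param cfg A [power_config()].
#' @param N Total sample size (`N >= 2k`).
#' @return Power (probability the noncentral F exceeds the central
#'   critical value).
#' @export
power_at <- function(cfg, N) {
  stopifnot(inherits(cfg, "power_config"), all(N >= 2 * cfg$k))
  df1 <- (cfg$k - 1) * (cfg$m - 1) * cfg$epsilon
  df2 <- (N - cfg$k) * (cfg$m - 1) * cfg$epsilon
  lambda <- N * cfg$effect_f^2 * cfg$m / (1 - cfg$rho) * cfg$epsilon
  crit <- stats::qf(1 - cfg$alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = lambda)
}

#' A priori sample size for the interaction effect
#'
#' Smallest balanced total N (a multiple of the number of groups) whose
#' interaction power reaches the target. With the trial's configuration
#' (f = 0.25, alpha = .05, power = .90, 2 groups, 2 measurements,
#' rho = 0) this returns N = 88.
#'
#' @param cfg A [power_config()].
#' @param max_n Search bound.
#' @return Total N.
#' @export
sample_size_rm_interaction <- function(cfg, max_n = 10000L) {
  stopifnot(inherits(cfg, "power_config"))
  for (N in seq(2L * cfg$k, max_n, by = cfg$k)) {
    if (power_at(cfg, N) >= cfg$target_power) return(N)
  }
  stop(sprintf(
    "target power %.2f not reachable with N <= %d at f = %g",
    cfg$target_power, max_n, cfg$effect_f
  ))
}

#' Monte-Carlo power of the interaction test
#'
#' Simulates raw pre/post data for two balanced groups (per-observation
#' error SD 1, within-subject correlation `rho`, interaction cell means
#' `+/- f`) and computes the rejection rate of the interaction F test.
#' For two measurements the mixed-ANOVA interaction F is identical to the
#' squared pooled two-sample t on the post-minus-pre change scores, which
#' is the statistic evaluated per replicate.
#'
#' @param cfg A [power_config()] (requires `k = 2`, `m = 2`).
#' @param N Total sample size (even).
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @return Estimated power.
#' @export
mc_power_interaction <- function(cfg, N, n_rep = 5000L, seed = NULL) {
  stopifnot(inherits(cfg, "power_config"), cfg$k == 2L, cfg$m == 2L,
            N %% 2L == 0L)
  with_seed(seed, {
    n <- N %/% 2L
    f <- cfg$effect_f
    # cell means: group 1 (pre -f, post +f), group 2 (pre +f, post -f)
    sim_group <- function(mu_pre, mu_post) {
      # correlated errors via shared subject component
      shared <- matrix(stats::rnorm(n_rep * n, 0, sqrt(cfg$rho)), n_rep, n)
      pre <- mu_pre + shared +
        matrix(stats::rnorm(n_rep * n, 0, sqrt(1 - cfg$rho)), n_rep, n)
      post <- mu_post + shared +
        matrix(stats::rnorm(n_rep * n, 0, sqrt(1 - cfg$rho)), n_rep, n)
      post - pre
    }
    d1 <- sim_group(-f, +f)
    d2 <- sim_group(+f, -f)
    m1 <- rowMeans(d1)
    m2 <- rowMeans(d2)
    v1 <- apply(d1, 1L, stats::var)
    v2 <- apply(d2, 1L, stats::var)
    sp2 <- ((n - 1) * v1 + (n - 1) * v2) / (N - 2)
    t2 <- (m1 - m2)^2 / (sp2 * 2 / n)
    crit <- stats::qf(1 - cfg$alpha, 1, N - 2)
    mean(t2 > crit)
  })
}
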