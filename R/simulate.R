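# Synthetic-data generators: minute-epoch actigraphy with a known extended
# cosine mean curve, a cohort layer with covariates / weights / eligibility
# flags, and biomarker panels whose abnormality follows a configured logit
# model. Ground truth is carried alongside so rhythm estimation and the
# association engine can be validated by parameter and odds-ratio recovery.

#' Ground-truth rhythm specification for the actigraphy generator
#'
#' Describes one participant's true 24-h activity process: the mean curve is
#' the sigmoidally-transformed extended cosine
#' `minimum + amplitude * antilogistic(cos(2 * pi * (t - acrophase) / 24),
#' alpha, beta)` with additive Gaussian noise truncated at zero. Sleep is a
#' fixed daily window; by default it is centred on the curve nadir
#' (`acrophase + 12`), so mean activity during sleep epochs sits near the
#' curve minimum. Non-wear blocks carry no activity value.
#'
#' @param minimum Curve nadir (activity units, `>= 0`).
#' @param amplitude Peak-to-nadir difference (activity units, `>= 0`); the
#'   noiseless daily maximum is `minimum + amplitude`.
#' @param acrophase Clock time of peak activity, hours in `[0, 24)`.
#' @param alpha Width parameter in `(-1, 1)`.
#' @param beta Steepness parameter `> 0`.
#' @param noise_sd SD of additive epoch noise (activity units, `>= 0`).
#' @param n_days Number of recorded days (integer `>= 1`).
#' @param sleep_window Length-2 numeric: onset clock hour in `[0, 24)` and
#'   duration in minutes (`<= 1440`). Defaults to an 8-h window centred on
#'   the curve nadir.
#' @param nonwear_blocks List of length-3 numerics `(day, start_minute,
#'   length_minutes)`; epochs inside a block are labelled `nonwear` and get a
#'   missing activity value. Blocks overlapping the sleep window are
#'   rejected.
#' @param noise Noise family: `"gaussian"` (default) or `"t"` (scaled
#'   Student-t with 4 df, a heavier-tailed alternative).
#' @return A validated list of class `rhythm_truth`.
#' @export
rhythm_truth <- function(minimum, amplitude, acrophase, alpha = 0, beta = 8,
                         noise_sd = 0, n_days = 7L,
                         sleep_window = NULL, nonwear_blocks = list(),
                         noise = c("gaussian", "t")) {
  noise <- match.arg(noise)
  if (minimum < 0 || amplitude < 0 || noise_sd < 0) {
    abort("`minimum`, `amplitude` and `noise_sd` must be non-negative.")
  }
  if (acrophase < 0 || acrophase >= 24) abort("`acrophase` must lie in [0, 24).")
  if (alpha <= -1 || alpha >= 1) abort("`alpha` must lie in (-1, 1).")
  if (beta <= 0) abort("`beta` must be positive.")
  if (n_days < 1) abort("`n_days` must be >= 1.")
  if (is.null(sleep_window)) {
    sleep_window <- c(((acrophase + 12) %% 24) - 4, 480)
    sleep_window[1] <- sleep_window[1] %% 24
  }
  if (length(sleep_window) != 2L || sleep_window[2] < 0 || sleep_window[2] > 1440) {
    abort("`sleep_window` must be (onset hour, duration minutes <= 1440).")
  }
  sleep_min <- sleep_minutes_of_day(sleep_window)
  for (blk in nonwear_blocks) {
    if (length(blk) != 3L || blk[1] < 1 || blk[1] > n_days ||
        blk[2] < 0 || blk[2] >= 1440 || blk[3] < 1) {
      abort("Each non-wear block must be (day in 1..n_days, start minute, length).")
    }
    blk_min <- (blk[2] + seq_len(blk[3]) - 1) %% 1440
    if (any(blk_min %in% sleep_min)) {
      abort("Non-wear block overlaps the sleep window; blocks must be disjoint.")
    }
  }
  structure(
    list(minimum = minimum, amplitude = amplitude, acrophase = acrophase,
         alpha = alpha, beta = beta, noise_sd = noise_sd,
         n_days = as.integer(n_days), sleep_window = sleep_window,
         nonwear_blocks = nonwear_blocks, noise = noise),
    class = "rhythm_truth"
  )
}

# Minutes-of-day covered by the (possibly midnight-wrapping) sleep window.
sleep_minutes_of_day <- function(sleep_window) {
  onset_min <- round(sleep_window[1] * 60)
  if (sleep_window[2] == 0) return(integer(0))
  (onset_min + seq_len(round(sleep_window[2])) - 1) %% 1440
}

#' Simulate minute-epoch actigraphy from a known rhythm
#'
#' Generates `1440 * n_days` one-minute epoch records whose noiseless mean
#' follows the ground-truth extended cosine curve. Sleep epochs fall inside
#' the daily sleep window, non-wear epochs inside the configured blocks
#' (with missing activity), and all remaining epochs are wake.
#'
#' @param truth A [rhythm_truth()] object.
#' @param participant_id Identifier copied into every record.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A tibble of epoch records: `participant_id`, `day_index`,
#'   `minute_of_day`, `activity`, `state`.
#' @export
simulate_actigraphy <- function(truth, participant_id, seed) {
  stopifnot(inherits(truth, "rhythm_truth"))
  n <- 1440L * truth$n_days
  day <- rep(seq_len(truth$n_days), each = 1440L)
  minute <- rep(0:1439, times = truth$n_days)
  t_hours <- minute / 60

  mean_act <- extended_cosine_curve(t_hours, truth$minimum, truth$amplitude,
                                    truth$acrophase, truth$alpha, truth$beta)
  activity <- withr::with_seed(seed, {
    eps <- if (truth$noise == "gaussian") {
      rnorm(n, 0, truth$noise_sd)
    } else {
      truth$noise_sd * stats::rt(n, df = 4) / sqrt(2) # scaled to unit variance
    }
    pmax(mean_act + eps, 0)
  })
  if (truth$noise_sd == 0) activity <- mean_act

  state <- rep("wake", n)
  state[minute %in% sleep_minutes_of_day(truth$sleep_window)] <- "sleep"
  for (blk in truth$nonwear_blocks) {
    idx <- (blk[1] - 1L) * 1440L + ((blk[2] + seq_len(blk[3]) - 1) %% 1440) + 1L
    state[idx] <- "nonwear"
  }
  activity[state == "nonwear"] <- NA_real_

  tibble::tibble(
    participant_id = participant_id,
    day_index = day,
    minute_of_day = minute,
    activity = activity,
    state = state
  )
}

# Names of the six liver biomarkers, in panel order.
BIOMARKERS <- c("alt", "ast", "alp", "ggt", "albumin", "bilirubin")

#' Configuration for the synthetic cohort and biomarker generators
#'
#' Bundles everything the cohort layer needs: size, covariate distributions,
#' true quintile log-odds per biomarker, baseline prevalences, the survey
#' weight distribution and eligibility (exclusion-cascade) rates. Defaults
#' emulate a US adult actigraphy cohort: age roughly uniform over 20-79 with
#' tails outside, lognormal weights normalized to mean 1, and small rates of
#' pregnancy, missing actigraphy, insufficient valid days and missing
#' biomarker panels.
#'
#' @param n_participants Cohort size (integer `>= 0`).
#' @param true_log_odds Named list, one entry per biomarker (subset of
#'   `alt, ast, alp, ggt, albumin, bilirubin`), each a length-5 numeric of
#'   log-odds contrasts by exposure quintile (reference quintile carries 0;
#'   by convention Q5). Missing biomarkers default to the null vector.
#' @param baseline_prevalence Named numeric of per-biomarker abnormality
#'   prevalence at the reference quintile, each in `(0, 1)`.
#' @param covariate_log_odds Optional named numeric of additional log-odds
#'   terms applied to all biomarkers: supported names `age_per10` (per
#'   decade, centred at 50) and `male`.
#' @param weight_distribution Length-2 numeric `(meanlog, sdlog)` of the
#'   lognormal survey-weight distribution before normalization to mean 1.
#' @param exclusion_rates Named numeric rates used to draw eligibility
#'   flags: `pregnant`, `no_actigraphy`, `few_valid_days`,
#'   `missing_biomarkers`.
#' @param age_range Length-2 numeric; ages are drawn uniformly over it
#'   (default 18-85, so the cascade's age rules bite).
#' @param seed Master seed; per-participant streams are derived from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          true_log_odds = list(),
                          baseline_prevalence = NULL,
                          covariate_log_odds = NULL,
                          weight_distribution = c(0, 0.5),
                          exclusion_rates = c(pregnant = 0.01,
                                              no_actigraphy = 0.10,
                                              few_valid_days = 0.08,
                                              missing_biomarkers = 0.03),
                          age_range = c(18, 85),
                          seed = 1L) {
  if (n_participants < 0) abort("`n_participants` must be >= 0.")
  if (is.null(baseline_prevalence)) {
    baseline_prevalence <- c(alt = 0.08, ast = 0.07, alp = 0.04,
                             ggt = 0.10, albumin = 0.02, bilirubin = 0.05)
  }
  bad <- setdiff(names(true_log_odds), BIOMARKERS)
  if (length(bad)) {
    abort(sprintf("Unknown biomarker in `true_log_odds`: %s.",
                  paste(bad, collapse = ", ")))
  }
  for (nm in names(true_log_odds)) {
    if (length(true_log_odds[[nm]]) != 5L) {
      abort("Each `true_log_odds` entry must have one value per quintile (5).")
    }
  }
  if (any(baseline_prevalence <= 0 | baseline_prevalence >= 1)) {
    abort("Baseline prevalences must lie in (0, 1).")
  }
  if (weight_distribution[2] < 0) abort("Weight sdlog must be >= 0.")
  structure(
    list(n_participants = as.integer(n_participants),
         true_log_odds = true_log_odds,
         baseline_prevalence = baseline_prevalence,
         covariate_log_odds = covariate_log_odds,
         weight_distribution = weight_distribution,
         exclusion_rates = exclusion_rates,
         age_range = age_range,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a cohort of participants
#'
#' Draws one row per participant: demographic and lifestyle covariates,
#' hepatitis serology, a positive survey weight, an exposure quintile (1-5,
#' uniform), per-participant ground-truth rhythm parameters (quintile-linked
#' noise so higher quintiles show more robust rhythms), and the eligibility
#' fields the exclusion cascade consumes (`age`, `pregnant`,
#' `has_actigraphy`, `n_valid_days`, `has_biomarkers`).
#'
#' @param config A [cohort_config()].
#' @return A tibble with `n_participants` rows; empty (zero-row, full
#'   schema) when `n_participants = 0`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  rates <- config$exclusion_rates
  out <- withr::with_seed(config$seed, {
    gender <- sample(c("male", "female"), n, replace = TRUE)
    age <- runif(n, config$age_range[1], config$age_range[2])
    quint <- sample(1:5, n, replace = TRUE)
    w <- rlnorm(n, config$weight_distribution[1], config$weight_distribution[2])
    tibble::tibble(
      participant_id = sprintf("P%05d", seq_len(n)),
      age = age,
      gender = gender,
      race = sample(c("nh_white", "nh_black", "hispanic", "other"), n,
                    replace = TRUE, prob = c(0.62, 0.13, 0.17, 0.08)),
      education = sample(c("lt_hs", "hs", "some_college", "college"), n,
                         replace = TRUE, prob = c(0.13, 0.23, 0.31, 0.33)),
      income = sample(c("lt20k", "20_45k", "45_75k", "75k_plus"), n,
                      replace = TRUE, prob = c(0.18, 0.27, 0.22, 0.33)),
      marital = sample(c("married", "not_married"), n, replace = TRUE,
                       prob = c(0.55, 0.45)),
      smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                       prob = c(0.56, 0.24, 0.20)),
      alcohol = sample(c("never_former", "light", "moderate", "heavy"), n,
                       replace = TRUE, prob = c(0.30, 0.35, 0.20, 0.15)),
      bmi_cat = sample(c("lt25", "25_30", "30_plus"), n, replace = TRUE,
                       prob = c(0.29, 0.33, 0.38)),
      diabetes = rbinom(n, 1, 0.12) == 1,
      hepatitis_b = rbinom(n, 1, 0.05) == 1,
      hepatitis_c = rbinom(n, 1, 0.02) == 1,
      hepatitis_e = rbinom(n, 1, 0.06) == 1,
      session = sample(c("morning", "afternoon", "evening"), n,
                       replace = TRUE, prob = c(0.45, 0.40, 0.15)),
      pregnant = gender == "female" & age < 45 &
        runif(n) < rates[["pregnant"]] /
          max(mean(gender == "female" & age < 45), 1e-9),
      weight = w / mean(w),
      exposure_quintile = quint,
      # truth: robustness (noise relative to amplitude) improves with quintile
      true_minimum = runif(n, 5, 20),
      true_amplitude = runif(n, 60, 140),
      true_acrophase = (14 + rnorm(n, 0, 1.5)) %% 24,
      true_alpha = runif(n, -0.4, 0.4),
      true_beta = runif(n, 4, 12),
      true_noise_sd = runif(n, 10, 25) * (1.6 - 0.2 * quint),
      has_actigraphy = runif(n) >= rates[["no_actigraphy"]],
      n_valid_days = ifelse(runif(n) < rates[["few_valid_days"]],
                            sample(0:3, n, replace = TRUE),
                            sample(4:7, n, replace = TRUE)),
      has_biomarkers = runif(n) >= rates[["missing_biomarkers"]]
    )
  })
  out$pregnant[is.na(out$pregnant)] <- FALSE
  out$n_valid_days[!out$has_actigraphy] <- 0L
  out
}

# Thresholds of the six liver-function markers; `direction` is the abnormal
# side, `male`/`female` the sex-specific cut-offs (strict inequalities).
liver_thresholds <- function() {
  tibble::tibble(
    biomarker = BIOMARKERS,
    direction = c("above", "above", "above", "above", "below", "above"),
    male      = c(47, 33, 113, 65, 3.7, 1.3),
    female    = c(30, 33, 113, 36, 3.7, 1.3)
  )
}

#' Simulate liver biomarker panels for a cohort
#'
#' For each biomarker, abnormal status is drawn from
#' `Bernoulli(plogis(logit(baseline) + quintile log-odds + covariate
#' terms))`, then a continuous level is sampled from the correct side of the
#' sex-specific clinical cut-off, so applying [abnormal_flags()] to the
#' generated levels reproduces the drawn status exactly.
#'
#' @param cohort Output of [simulate_cohort()] (needs `exposure_quintile`,
#'   `gender`, `age`, `has_biomarkers`, `participant_id`).
#' @param config The same [cohort_config()].
#' @param seed Integer seed for the biomarker draw.
#' @return A tibble keyed by `participant_id` with `sex`, the six level
#'   columns (`alt`, `ast`, `alp`, `ggt` in IU/L; `albumin` in g/dL;
#'   `bilirubin` in mg/dL) and the drawn `abnormal_*` indicator columns.
#'   Participants without a biomarker panel get missing levels.
#' @export
simulate_biomarkers <- function(cohort, config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!all(c("exposure_quintile", "gender") %in% names(cohort))) {
    abort("`cohort` must carry `exposure_quintile` and `gender`.")
  }
  n <- nrow(cohort)
  thr <- liver_thresholds()
  cov_lo <- config$covariate_log_odds
  lin_cov <- rep(0, n)
  if (!is.null(cov_lo)) {
    if ("age_per10" %in% names(cov_lo)) {
      lin_cov <- lin_cov + cov_lo[["age_per10"]] * (cohort$age - 50) / 10
    }
    if ("male" %in% names(cov_lo)) {
      lin_cov <- lin_cov + cov_lo[["male"]] * (cohort$gender == "male")
    }
  }

  out <- tibble::tibble(participant_id = cohort$participant_id,
                        sex = cohort$gender)
  withr::with_seed(seed, {
    for (bm in BIOMARKERS) {
      lo <- config$true_log_odds[[bm]] %||% rep(0, 5)
      eta <- stats::qlogis(config$baseline_prevalence[[bm]]) +
        lo[cohort$exposure_quintile] + lin_cov
      abn <- rbinom(n, 1, stats::plogis(eta)) == 1
      row <- thr[thr$biomarker == bm, ]
      cut <- ifelse(cohort$gender == "male", row$male, row$female)
      lvl <- if (row$direction == "above") {
        ifelse(abn,
               cut * exp(abs(rnorm(n, 0, 0.3)) + 1e-4),
               cut * runif(n, 0.25, 1))
      } else {
        ifelse(abn,
               pmax(cut - abs(rnorm(n, 0, 0.35)) - 1e-4, cut * 0.3),
               cut + runif(n, 0.01, 1.6))
      }
      lvl[!cohort$has_biomarkers] <- NA_real_
      abn[!cohort$has_biomarkers] <- NA
      out[[bm]] <- lvl
      out[[paste0("abnormal_", bm)]] <- abn
    }
  })
  out
}
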