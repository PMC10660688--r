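# Shared fixture builders: everything is generated in code at test time.

# Hand-built epoch tibble for one participant: `spec` is a list of per-day
# lists with vectors `activity` (length 1440) and `state`.
make_epochs <- function(days, participant_id = "p1") {
  purrr::imap_dfr(days, function(day, i) {
    tibble::tibble(
      participant_id = participant_id,
      day_index = i,
      minute_of_day = 0:1439,
      activity = day$activity,
      state = day$state
    )
  })
}

# A full wake day with the given constant activity.
wake_day <- function(activity = 1) {
  list(activity = rep(activity, 1440), state = rep("wake", 1440))
}

default_truth <- function(...) {
  args <- utils::modifyList(
    list(minimum = 10, amplitude = 100, acrophase = 14, alpha = 0, beta = 8,
         noise_sd = 5, n_days = 7L),
    list(...)
  )
  do.call(rhythm_truth, args)
}

# Hourly-series tibble in the hourly_means() layout.
make_hourly <- function(activity, n_days = length(activity) %/% 24) {
  tibble::tibble(
    participant_id = "p1",
    day_index = rep(seq_len(n_days), each = 24),
    hour = rep(0:23, times = n_days),
    activity = activity
  )
}

# Bin table (one participant, one day) from a 288-long activity profile.
make_bins <- function(profile, day = 1L) {
  tibble::tibble(
    participant_id = "p1",
    day_index = day,
    bin = 0:287,
    activity = profile,
    minute_of_day = (0:287) * 5L,
    time = (day - 1) * 24 + (0:287) * 5 / 60
  )
}

# Peak-minus-nadir range and nadir level of a truth curve on the same
# 1-minute grid the fitter reports from (the raw amplitude parameter is the
# asymptotic range, which the anti-logistic link never fully attains).
curve_range_for_test <- function(minimum, amplitude, acrophase, alpha, beta) {
  g <- seq(0, 24 - 1 / 60, by = 1 / 60)
  y <- minimum + amplitude * antilogistic(cos((g - acrophase) * pi / 12),
                                          alpha, beta)
  c(nadir = min(y), amp = max(y) - min(y))
}

circular_dist_for_test <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

# Cohort + biomarkers joined into one analysis table.
make_analysis_table <- function(n, true_log_odds = list(), seed = 1,
                                baseline_prevalence = NULL, ...) {
  cfg <- cohort_config(n, true_log_odds = true_log_odds,
                       baseline_prevalence = baseline_prevalence,
                       seed = seed, ...)
  coh <- simulate_cohort(cfg)
  bm <- simulate_biomarkers(coh, cfg, seed = seed + 1)
  dplyr::bind_cols(coh, bm[, setdiff(names(bm), "participant_id")])
}
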