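# Non-parametric rest-activity metrics: interdaily stability (IS),
# intradaily variability (IV), the L5 midpoint (centre of the least-active
# 5 consecutive hours) and the circular-statistics rule flagging night-shift
# work / unconventional sleep timing.

#' Hourly means from 5-minute bins
#'
#' IS and IV are computed on 60-minute means (the dominant convention for
#' these statistics), built here from the 5-minute bins; an hour is missing
#' when all of its twelve bins are. The bin width is a knob: any divisor of
#' the day expressible in whole 5-minute bins works (e.g. 30 or 120 min),
#' with the slot index taking the place of the hour.
#'
#' @param bins Output of [aggregate_5min()].
#' @param bin_minutes Width of the coarse bins in minutes (default 60; must
#'   be a multiple of 5 dividing 1440).
#' @return A tibble per (participant, day, slot) with `hour` (slot index,
#'   0-23 for the default width) and `activity`.
#' @export
hourly_means <- function(bins, bin_minutes = 60L) {
  if (bin_minutes %% 5 != 0 || 1440 %% bin_minutes != 0) {
    abort("`bin_minutes` must be a multiple of 5 that divides 1440.")
  }
  per <- bin_minutes %/% 5L
  bins |>
    dplyr::mutate(hour = .data$bin %/% .env$per) |>
    dplyr::group_by(.data$participant_id, .data$day_index, .data$hour) |>
    dplyr::summarise(
      activity = if (all(is.na(.data$activity))) NA_real_
                 else mean(.data$activity, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Interdaily stability
#'
#' `IS = (hour-of-day variance) / (total variance)`: the mean squared
#' deviation of the 24 hourly profile means about the grand mean, divided by
#' the mean squared deviation of every hourly value about the grand mean.
#' A perfectly repeating daily pattern gives 1; independent noise over `d`
#' days gives about `1/d`.
#'
#' @param hourly Hourly series for one participant ([hourly_means()] layout:
#'   `day_index`, `hour`, `activity`).
#' @return IS in `[0, 1]`; `NA` (with a warning) for a constant series.
#' @export
interdaily_stability <- function(hourly) {
  x <- hourly$activity
  keep <- !is.na(x)
  x <- x[keep]
  h <- hourly$hour[keep]
  n <- length(x)
  if (n == 0) return(NA_real_)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2) / n
  if (denom <= 0) {
    warn("Constant hourly series: IS undefined.")
    return(NA_real_)
  }
  profile <- tapply(x, h, mean)
  num <- sum((profile - xbar)^2) / length(profile)
  num / denom
}

#' Intradaily variability
#'
#' `IV = (mean squared successive difference) / (variance)` of the
#' concatenated valid-day hourly series. Differences are taken only between
#' truly adjacent hours (consecutive hour slots, including across a boundary
#' between consecutive days); gaps from missing hours or missing days
#' contribute no difference. White noise gives about 2, a smooth sinusoid
#' much less, fragmented rhythms more.
#'
#' @param hourly Hourly series for one participant.
#' @return IV (`>= 0`); `NA` with a warning for a constant series or when no
#'   adjacent pair exists.
#' @export
intradaily_variability <- function(hourly) {
  hourly <- dplyr::arrange(hourly, .data$day_index, .data$hour)
  slots_per_day <- max(24L, max(hourly$hour, na.rm = TRUE) + 1L)
  slot <- hourly$day_index * slots_per_day + hourly$hour
  x <- hourly$activity
  keep <- !is.na(x)
  x <- x[keep]
  slot <- slot[keep]
  n <- length(x)
  if (n < 2) return(NA_real_)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2) / n
  if (denom <= 0) {
    warn("Constant hourly series: IV undefined.")
    return(NA_real_)
  }
  adj <- which(diff(slot) == 1L)
  if (!length(adj)) {
    warn("No adjacent hour pairs: IV undefined.")
    return(NA_real_)
  }
  d <- x[adj + 1L] - x[adj]
  (sum(d^2) / length(d)) / denom
}

#' L5 midpoint: centre of the least-active 5 consecutive hours
#'
#' The 24-h average activity profile over valid days is scanned with a 5-h
#' window advancing in 5-minute steps and wrapping midnight; the returned
#' midpoint is the centre of the window with the lowest mean activity
#' (earliest window on ties).
#'
#' @param bins [aggregate_5min()] output for one participant.
#' @param profile `"average"` (default) scans the across-days average
#'   profile — the stabler convention; `"per_day"` finds each valid day's
#'   window and returns the circular mean of the daily midpoints (the mean
#'   activity is then averaged over days).
#' @return A one-row tibble: `l5_midpoint` (clock hours in `[0, 24)`) and
#'   `l5_mean_activity`; both `NA` when more than half of the 288 profile
#'   bins are missing.
#' @export
l5_midpoint <- function(bins, profile = c("average", "per_day")) {
  profile <- match.arg(profile)
  if (profile == "per_day") {
    per_day <- bins |>
      dplyr::group_by(.data$day_index) |>
      tidyr::nest() |>
      dplyr::ungroup() |>
      dplyr::mutate(res = purrr::map(.data$data, l5_midpoint)) |>
      dplyr::select("res") |>
      tidyr::unnest("res") |>
      dplyr::filter(!is.na(.data$l5_midpoint))
    if (!nrow(per_day)) {
      return(tibble::tibble(l5_midpoint = NA_real_,
                            l5_mean_activity = NA_real_))
    }
    a <- hours_to_angle(per_day$l5_midpoint)
    mid <- angle_to_hours(atan2(mean(sin(a)), mean(cos(a))))
    return(tibble::tibble(l5_midpoint = mid,
                          l5_mean_activity = mean(per_day$l5_mean_activity)))
  }
  prof <- bins |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      activity = if (all(is.na(.data$activity))) NA_real_
                 else mean(.data$activity, na.rm = TRUE),
      .groups = "drop"
    )
  profile <- rep(NA_real_, 288)
  profile[prof$bin + 1L] <- prof$activity
  if (mean(is.na(profile)) > 0.5) {
    return(tibble::tibble(l5_midpoint = NA_real_, l5_mean_activity = NA_real_))
  }
  wrapped <- c(profile, profile[1:59])
  win_mean <- vapply(1:288, function(s) {
    w <- wrapped[s:(s + 59)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  s <- which.min(win_mean) # earliest minimum on ties
  midpoint <- (((s - 1) * 5 + 150) / 60) %% 24
  tibble::tibble(l5_midpoint = midpoint, l5_mean_activity = win_mean[s])
}

#' Flag night-shift work / unconventional sleep timing
#'
#' With no occupational data available, participants whose L5 midpoint lies
#' more than two circular standard deviations from the cohort's circular
#' median midpoint are flagged as probable night-shift workers or people
#' with unconventional sleep timing. Distances, the median and the SD are
#' all computed on the 24-h circle, so a midpoint near midnight is handled
#' correctly. The flag uses a strict inequality, so a zero-spread cohort
#' flags no one.
#'
#' @param l5 Numeric vector of L5 midpoints (hours), one per participant.
#' @return Logical vector; `NA` midpoints give `NA` flags.
#' @export
flag_shift_workers <- function(l5) {
  ok <- !is.na(l5)
  if (sum(ok) < 10) {
    abort("Fewer than 10 L5 midpoints: the cohort dispersion is too unstable to flag.")
  }
  med <- circular_median_hours(l5[ok])
  sdv <- circular_sd_hours(l5[ok])
  out <- rep(NA, length(l5))
  out[ok] <- circular_distance_hours(l5[ok], med) > 2 * sdv
  out
}

#' Non-parametric metrics for every participant in a bin table
#'
#' @param bins [aggregate_5min()] output (any number of participants).
#' @param bin_minutes Coarse bin width for IS/IV (see [hourly_means()]).
#' @param l5_profile Profile convention for the L5 window (see
#'   [l5_midpoint()]).
#' @return A tibble per participant: `IS`, `IV`, `l5_midpoint`,
#'   `l5_mean_activity`.
#' @export
nonparametric_by_participant <- function(bins, bin_minutes = 60L,
                                         l5_profile = "average") {
  hourly <- hourly_means(bins, bin_minutes)
  isiv <- hourly |>
    dplyr::group_by(.data$participant_id) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(
      IS = purrr::map_dbl(.data$data, interdaily_stability),
      IV = purrr::map_dbl(.data$data, intradaily_variability)
    ) |>
    dplyr::select("participant_id", "IS", "IV")
  l5 <- bins |>
    dplyr::group_by(.data$participant_id) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(l5 = purrr::map(.data$data, l5_midpoint,
                                  profile = l5_profile)) |>
    dplyr::select("participant_id", "l5") |>
    tidyr::unnest("l5")
  dplyr::left_join(isiv, l5, by = "participant_id")
}
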