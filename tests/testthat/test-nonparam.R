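test_that("IS is 1 for a repeating pattern and undefined for a constant", {
  pattern <- sin(2 * pi * (0:23) / 24) + 2
  h <- make_hourly(rep(pattern, 5))
  expect_equal(interdaily_stability(h), 1, tolerance = 1e-12)
  expect_warning(is_c <- interdaily_stability(make_hourly(rep(3, 72))),
                 "undefined")
  expect_true(is.na(is_c))
})

test_that("IS of iid noise over d days concentrates near 1/d", {
  vals <- withr::with_seed(42, vapply(1:60, function(i) {
    interdaily_stability(make_hourly(rnorm(7 * 24)))
  }, numeric(1)))
  expect_lt(abs(mean(vals) - 1 / 7), 0.03)
})

test_that("IV closed forms: alternating series 4, smooth sinusoid small", {
  h <- make_hourly(rep(c(0, 1), 36))
  expect_equal(intradaily_variability(h), 4, tolerance = 1e-12)
  sm <- make_hourly(sin(2 * pi * (0:71) / 24))
  expect_lt(intradaily_variability(sm), 0.5)
  expect_warning(iv_c <- intradaily_variability(make_hourly(rep(2, 48))),
                 "undefined")
  expect_true(is.na(iv_c))
})

test_that("IV takes no differences across gaps", {
  x <- rep(c(0, 1), 24)
  h <- make_hourly(x, n_days = 2)
  h_gap <- h[-(20:30), ] # missing block within day 1
  iv_full <- intradaily_variability(h)
  iv_gap <- intradaily_variability(h_gap)
  expect_false(is.na(iv_gap))
  # all surviving adjacent pairs still differ by 1: MSSD unchanged
  expect_equal(iv_gap * (sum((h_gap$activity - mean(h_gap$activity))^2) /
                           nrow(h_gap)), 1, tolerance = 1e-12)
  expect_false(is.na(iv_full))
})

test_that("IS and IV are invariant to rescaling and day relabeling", {
  h <- make_hourly(withr::with_seed(9, rnorm(7 * 24, 10, 3)))
  h2 <- dplyr::mutate(h, activity = activity * 7.3)
  expect_equal(interdaily_stability(h), interdaily_stability(h2))
  expect_equal(intradaily_variability(h), intradaily_variability(h2))
  h3 <- dplyr::mutate(h, day_index = day_index + 10)
  expect_equal(interdaily_stability(h), interdaily_stability(h3))
})

test_that("IS changes under within-day hour shuffles but not day swaps", {
  pattern <- 10 + 8 * sin(2 * pi * (0:23) / 24)
  h <- make_hourly(rep(pattern, 5) + withr::with_seed(3, rnorm(120, 0, 0.5)))
  is0 <- interdaily_stability(h)
  perm <- withr::with_seed(4, sample(24))
  h_hours <- h |>
    dplyr::group_by(day_index) |>
    dplyr::mutate(activity = activity[perm[hour + 1]]) |>
    dplyr::ungroup()
  # one shared permutation of hour labels reassigns which hour holds which
  # value but keeps days aligned, so IS is unchanged; permuting hours
  # independently per day destroys the alignment
  h_indep <- withr::with_seed(5, h |>
    dplyr::group_by(day_index) |>
    dplyr::mutate(activity = sample(activity)) |>
    dplyr::ungroup())
  h_days <- h |>
    dplyr::mutate(day_index = dplyr::recode(day_index, `1` = 3L, `3` = 1L))
  expect_equal(interdaily_stability(h_hours), is0, tolerance = 1e-12)
  expect_lt(interdaily_stability(h_indep), is0)
  expect_equal(interdaily_stability(h_days), is0, tolerance = 1e-12)
})

test_that("L5 midpoint honors plain and midnight-wrapping troughs", {
  prof <- rep(10, 288)
  prof[1:60] <- 0 # [0:00, 5:00)
  expect_equal(l5_midpoint(make_bins(prof))$l5_midpoint, 2.5)

  prof2 <- rep(10, 288)
  prof2[c(265:288, 1:36)] <- 0 # [22:00, 3:00)
  res <- l5_midpoint(make_bins(prof2))
  expect_equal(res$l5_midpoint, 0.5)
  expect_equal(res$l5_mean_activity, 0)

  mostly_na <- make_bins(c(rep(NA_real_, 150), rep(1, 138)))
  expect_true(is.na(l5_midpoint(mostly_na)$l5_midpoint))
})

test_that("L5 midpoint sits opposite the acrophase for a smooth rhythm", {
  truth <- default_truth(beta = 1, noise_sd = 0, n_days = 4L)
  bins <- aggregate_5min(simulate_actigraphy(truth, "p", seed = 1))
  mid <- nonparametric_by_participant(bins)$l5_midpoint
  expect_lt(circular_dist_for_test(mid, (14 + 12) %% 24), 0.5)
})

test_that("L5 midpoint is equivariant to circular shifts of the profile", {
  prof <- 10 + 8 * sin(2 * pi * (0:287) / 288)
  m0 <- l5_midpoint(make_bins(prof))$l5_midpoint
  shift_bins <- 36 # 3 h
  m1 <- l5_midpoint(make_bins(prof[((0:287 - shift_bins) %% 288) + 1]))$l5_midpoint
  expect_equal((m1 - m0) %% 24, 3, tolerance = 1e-9)
})

test_that("shift-worker flagging uses circular distance from the median", {
  l5 <- c(rep(2.5, 19), 14.5)
  flags <- flag_shift_workers(l5 + c(withr::with_seed(2, rnorm(19, 0, 0.3)), 0))
  expect_true(flags[20])
  expect_equal(sum(flags[1:19]), 0)

  expect_equal(sum(flag_shift_workers(rep(3, 15))), 0) # zero spread: none
  expect_error(flag_shift_workers(rep(3, 5)), "Fewer than 10")
})

test_that("a 12-h offset subpopulation is flagged at its true rate", {
  n <- 2000
  l5 <- withr::with_seed(8, {
    night <- runif(n) < 0.05
    (ifelse(night, 14, 2) + rnorm(n, 0, 0.8)) %% 24
  })
  flags <- flag_shift_workers(l5)
  expect_lt(abs(mean(flags) - 0.05), 0.02)
})

test_that("coarser IS/IV bins and the per-day L5 variant behave sensibly", {
  truth <- default_truth(beta = 1, noise_sd = 0, n_days = 4L)
  bins <- aggregate_5min(simulate_actigraphy(truth, "p", seed = 13))
  expect_error(hourly_means(bins, bin_minutes = 7), "multiple of 5")
  h120 <- hourly_means(bins, bin_minutes = 120L)
  expect_equal(sort(unique(h120$hour)), 0:11)
  # noiseless repeating days: IS = 1 at any bin width
  expect_equal(interdaily_stability(h120), 1, tolerance = 1e-12)

  avg <- l5_midpoint(bins)
  per <- l5_midpoint(bins, profile = "per_day")
  # identical days: both conventions find the same trough
  expect_lt(circular_dist_for_test(avg$l5_midpoint, per$l5_midpoint), 0.1)
})
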