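test_that("antilogistic closed forms and parameter validation", {
  expect_equal(antilogistic(0.3, alpha = 0.3, beta = 5), 0.5)
  expect_equal(antilogistic(1, alpha = 0, beta = 1), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  # square-wave limit: steep beta saturates on either side of alpha
  expect_equal(antilogistic(0.5, alpha = 0, beta = 1e4), 1)
  expect_equal(antilogistic(-0.5, alpha = 0, beta = 1e4), 0)
  expect_true(all(diff(antilogistic(seq(-1, 1, 0.1), 0.2, 3)) > 0))
  expect_error(antilogistic(0, alpha = 1, beta = 2), "alpha")
  expect_error(antilogistic(0, alpha = 0, beta = 0), "beta")
})

test_that("predicted curve peaks at the acrophase and is 24-h periodic", {
  fit <- extended_cosine_fit(minimum = 5, amplitude = 80, acrophase = 15,
                             alpha = 0.2, beta = 3)
  t <- seq(0, 24, by = 1 / 60)
  y <- predict(fit, t)
  expect_equal(t[which.max(y)] %% 24, 15, tolerance = 1 / 60)
  expect_equal(t[which.min(y)] %% 24, 3, tolerance = 1 / 60)
  expect_equal(predict(fit, t), predict(fit, t + 24), tolerance = 1e-12)
  expect_equal(fit$mesor, 5 + 40)
})

test_that("noiseless curves are recovered to optimizer tolerance", {
  # exact curve samples: the optimizer itself introduces negligible error
  t <- seq(0.5 / 12, 96, by = 1 / 12)
  truth <- extended_cosine_fit(minimum = 10, amplitude = 100, acrophase = 14,
                               alpha = 0.2, beta = 8)
  fit <- fit_extended_cosine(tibble::tibble(time = t, activity = predict(truth, t)))
  expect_true(fit$converged)
  tr <- curve_range_for_test(10, 100, 14, 0.2, 8)
  expect_equal(fit$rss, 0, tolerance = 1e-8)
  expect_equal(fit$minimum, unname(tr["nadir"]), tolerance = 1e-6)
  expect_equal(fit$amplitude, unname(tr["amp"]), tolerance = 1e-6)
  expect_equal(fit$acrophase, truth$acrophase, tolerance = 1e-3)

  # through the epoch generator and 5-min binning: discretization keeps
  # recovery within a fraction of a percent
  truth2 <- default_truth(noise_sd = 0, n_days = 4L)
  fit2 <- fit_extended_cosine(
    aggregate_5min(simulate_actigraphy(truth2, "p1", seed = 1))
  )
  tr2 <- curve_range_for_test(10, 100, 14, 0, 8)
  expect_equal(fit2$minimum, unname(tr2["nadir"]), tolerance = 2e-3)
  expect_equal(fit2$amplitude, unname(tr2["amp"]), tolerance = 2e-3)
  expect_lt(abs(fit2$acrophase - truth2$acrophase), 0.05)
  # near-perfect fit: pseudo-F explodes relative to any noisy series
  expect_gt(fit2$pseudo_F, 1e6)
})

test_that("fits are equivariant to time shifts and positive scaling", {
  truth <- default_truth(noise_sd = 8, n_days = 4L)
  bins <- aggregate_5min(simulate_actigraphy(truth, "p1", seed = 7))
  fit <- fit_extended_cosine(bins)

  shifted <- dplyr::mutate(bins, time = time + 3)
  fit_s <- fit_extended_cosine(shifted)
  expect_equal(fit_s$acrophase, (fit$acrophase + 3) %% 24, tolerance = 0.02)
  expect_equal(fit_s$amplitude, fit$amplitude, tolerance = 1e-3)
  expect_equal(fit_s$pseudo_F, fit$pseudo_F, tolerance = 1e-3)

  scaled <- dplyr::mutate(bins, activity = activity * 3.5)
  fit_k <- fit_extended_cosine(scaled)
  expect_equal(fit_k$minimum, 3.5 * fit$minimum, tolerance = 1e-2)
  expect_equal(fit_k$amplitude, 3.5 * fit$amplitude, tolerance = 1e-3)
  expect_equal(fit_k$mesor, 3.5 * fit$mesor, tolerance = 1e-3)
  expect_equal(fit_k$acrophase, fit$acrophase, tolerance = 0.02)
  expect_equal(fit_k$alpha, fit$alpha, tolerance = 0.05)
  expect_equal(fit_k$beta, fit$beta, tolerance = 0.2)
  expect_equal(fit_k$pseudo_F, fit$pseudo_F, tolerance = 1e-3)
})

test_that("mesor identity holds for every emitted fit", {
  for (seed in 1:5) {
    truth <- default_truth(
      minimum = runif(1, 0, 30), amplitude = runif(1, 40, 150),
      acrophase = runif(1, 0, 24), alpha = runif(1, -0.5, 0.5),
      beta = runif(1, 1, 12), noise_sd = runif(1, 2, 20), n_days = 4L
    )
    fit <- fit_extended_cosine(
      aggregate_5min(simulate_actigraphy(truth, "p", seed = seed))
    )
    expect_equal(fit$mesor, fit$minimum + fit$amplitude / 2, tolerance = 1e-12)
    expect_lte(fit$rss, fit$rss_null + 1e-8)
    if (fit$minimum >= 0) expect_lte(fit$amp_mesor_ratio, 2 + 1e-12)
  }
})

test_that("pseudo-F is zero for a constant series and errors when n <= k", {
  flat <- extended_cosine_fit(minimum = 7, amplitude = 0, acrophase = 0,
                              alpha = 0, beta = 2)
  t <- seq(0, 96, by = 1 / 12)
  expect_equal(pseudo_f(flat, t, rep(7, length(t))), 0)
  expect_error(pseudo_f(flat, 1:5, c(1, 2, 1, 2, 1)), "observations")
})

test_that("pseudo-F increases as noise shrinks and beats pure noise", {
  f_at_noise <- function(noise_sd, seed) {
    truth <- default_truth(noise_sd = noise_sd, n_days = 4L)
    fit_extended_cosine(
      aggregate_5min(simulate_actigraphy(truth, "p", seed = seed))
    )$pseudo_F
  }
  low <- vapply(1:5, function(s) f_at_noise(10, s), numeric(1))
  high <- vapply(1:5, function(s) f_at_noise(40, s), numeric(1))
  expect_gt(median(low), median(high))

  # pure noise with the same variance as a rhythmic series scores far lower
  withr::with_seed(11, {
    t <- rep(seq(0, 24 - 1 / 12, by = 1 / 12), 4)
    rhythm <- 50 + 40 * cos((t - 14) * pi / 12) + rnorm(length(t), 0, 10)
    noise <- rnorm(length(t), mean(rhythm), sd(rhythm))
    f_r <- fit_extended_cosine(tibble::tibble(time = t, activity = rhythm))$pseudo_F
    f_n <- fit_extended_cosine(tibble::tibble(time = t, activity = noise))$pseudo_F
    expect_gt(f_r, f_n)
  })
})

test_that("fitting refuses an underpopulated series", {
  bins <- tibble::tibble(time = seq(0, 24, by = 0.5),
                         activity = rnorm(49, 10, 1))
  expect_error(fit_extended_cosine(bins), "Too few")
})

test_that("tidy and glance expose the fit as tibbles", {
  truth <- default_truth(noise_sd = 5, n_days = 4L)
  fit <- fit_extended_cosine(
    aggregate_5min(simulate_actigraphy(truth, "p", seed = 2))
  )
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("minimum", "amplitude", "acrophase", "alpha",
                             "beta", "mesor", "amp_mesor_ratio"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
})
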