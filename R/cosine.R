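#' Anti-logistic (sigmoidal) transform of the cosine term
#'
#' Maps the raw cosine `c` through a logistic link,
#' `exp(beta * (c - alpha)) / (1 + exp(beta * (c - alpha)))`, so the fitted
#' 24-h curve can range from a near-sinusoid (small `beta`) to a near-square
#' wave (large `beta`). `alpha` sets where on the cosine the curve crosses
#' half height and hence controls the width of the elevated (active) portion
#' of the day; `beta` controls the steepness of the rise and fall.
#'
#' @param c Numeric; the raw cosine value(s), typically in `[-1, 1]`.
#' @param alpha Width parameter, must lie in `(-1, 1)`.
#' @param beta Steepness parameter, must be `> 0`.
#' @return Values in `(0, 1)`, monotone increasing in `c`.
#' @examples
#' antilogistic(0, alpha = 0, beta = 2)   # 0.5 at c = alpha
#' antilogistic(1, alpha = 0, beta = 1)   # plogis(1)
#' @export
antilogistic <- function(c, alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= -1 || alpha >= 1) {
    abort("`alpha` must be a single number in (-1, 1).")
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    abort("`beta` must be a single positive number.")
  }
  # plogis is the numerically stable logistic CDF
  stats::plogis(beta * (c - alpha))
}

# Mean curve shared by the generator and the fitter: activity at clock time
# t (hours) for the sigmoidally-transformed extended cosine model.
extended_cosine_curve <- function(t, minimum, amplitude, acrophase, alpha, beta) {
  minimum + amplitude * antilogistic(cos((t - acrophase) * pi / 12), alpha, beta)
}

#' Construct an extended cosine fit object
#'
#' Mostly used internally by [fit_extended_cosine()]; exposed so that known
#' parameter sets (e.g. simulation ground truth) can be evaluated with
#' [predict.extended_cosine_fit()].
#'
#' @param minimum Curve nadir level (activity units).
#' @param amplitude Peak-to-nadir difference (activity units, `>= 0`).
#' @param acrophase Clock time of peak activity, hours in `[0, 24)`.
#' @param alpha,beta Shape parameters of the anti-logistic link.
#' @param rss,rss_null Residual sums of squares of the fitted and flat-mean
#'   models (may be `NA` for a ground-truth object).
#' @param n_obs Number of observations used in the fit.
#' @param converged Logical optimizer status.
#' @return An object of class `extended_cosine_fit` with derived fields
#'   `mesor = minimum + amplitude / 2`, `amp_mesor_ratio` and `pseudo_F`.
#' @export
extended_cosine_fit <- function(minimum, amplitude, acrophase, alpha, beta,
                                rss = NA_real_, rss_null = NA_real_,
                                n_obs = NA_integer_, converged = NA) {
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  mesor <- minimum + amplitude / 2
  f <- if (is.na(rss) || is.na(rss_null) || is.na(n_obs)) {
    NA_real_
  } else {
    pseudo_f_statistic(rss, rss_null, n_obs)
  }
  structure(
    list(
      minimum = minimum, amplitude = amplitude,
      acrophase = acrophase %% 24, alpha = alpha, beta = beta,
      mesor = mesor,
      amp_mesor_ratio = if (mesor != 0) amplitude / mesor else NA_real_,
      pseudo_F = f, rss = rss, rss_null = rss_null,
      n_obs = n_obs, converged = converged
    ),
    class = "extended_cosine_fit"
  )
}

#' Predict activity from an extended cosine fit
#'
#' @param object An `extended_cosine_fit`.
#' @param t Clock times in hours (any real; the curve is 24-h periodic).
#' @param ... Unused.
#' @return Predicted activity (same units as the fitted series).
#' @export
predict.extended_cosine_fit <- function(object, t, ...) {
  extended_cosine_curve(t, object$minimum, object$amplitude,
                        object$acrophase, object$alpha, object$beta)
}

#' @export
print.extended_cosine_fit <- function(x, ...) {
  cat("Sigmoidally-transformed extended cosine fit\n")
  cat(sprintf("  minimum %.3f  amplitude %.3f  mesor %.3f  amp:mesor %.3f\n",
              x$minimum, x$amplitude, x$mesor, x$amp_mesor_ratio))
  cat(sprintf("  acrophase %.2f h  alpha %.3f  beta %.3f\n",
              x$acrophase, x$alpha, x$beta))
  cat(sprintf("  pseudo-F %.2f on %d obs (converged: %s)\n",
              x$pseudo_F, x$n_obs, x$converged))
  invisible(x)
}

# Pseudo-F: flat-mean null (1 parameter) against the 5-parameter curve.
pseudo_f_statistic <- function(rss, rss_null, n_obs, k = 5L) {
  if (n_obs <= k) abort("pseudo-F requires more observations than parameters.")
  num <- (rss_null - rss) / (k - 1L)
  den <- rss / (n_obs - k)
  if (num <= 0) return(0) # flat fit: no improvement over the mean
  if (den <= 0) return(Inf)
  num / den
}

#' Pseudo-F rhythmicity statistic of a fitted curve against a series
#'
#' Goodness-of-fit ratio comparing the extended cosine model with a
#' flat-mean model: `F = [(RSS0 - RSS)/(k - 1)] / [RSS/(n - k)]` with
#' `k = 5` curve parameters. Higher values indicate a more robust overall
#' rest-activity rhythm; a constant series yields 0.
#'
#' @param fit An `extended_cosine_fit`.
#' @param time Clock times (hours) of the observations.
#' @param activity Observed activity at those times.
#' @return The pseudo-F statistic (dimensionless, `>= 0`).
#' @export
pseudo_f <- function(fit, time, activity) {
  keep <- !is.na(activity)
  time <- time[keep]
  activity <- activity[keep]
  rss <- sum((activity - predict(fit, time))^2)
  rss_null <- sum((activity - mean(activity))^2)
  pseudo_f_statistic(rss, rss_null, length(activity))
}

#' Fit the sigmoidally-transformed extended cosine model
#'
#' Least-squares fit of `minimum + amplitude * antilogistic(cos((t -
#' acrophase) * pi/12), alpha, beta)` to a participant's 5-minute binned
#' activity series over valid days. The objective is multimodal in the
#' acrophase, so a multi-start strategy is used: bounded Levenberg-Marquardt
#' from a grid of acrophase starts every 2 h crossed with
#' `alpha` in `{-0.6, 0, 0.6}`, keeping the best-RSS solution. `minimum` and
#' `amplitude` start from the series 5th percentile and 90% central spread;
#' `beta` starts at 2 and is bounded to `[0.1, 50]` so the optimizer cannot
#' chase a degenerate step function.
#'
#' @param data Data frame of binned activity, one row per bin, with columns
#'   `time` (clock hours since the first midnight; only `time %% 24` enters
#'   the curve) and `activity` (bin mean, `NA` allowed and dropped).
#'   [aggregate_5min()] emits this layout.
#' @param min_obs Minimum number of non-missing bins required
#'   (default 576, two days' worth of 5-minute bins).
#' @return An `extended_cosine_fit`; inspect with [tidy()]/[glance()].
#' @examples
#' truth <- rhythm_truth(minimum = 10, amplitude = 100, acrophase = 14,
#'                       alpha = 0, beta = 8, noise_sd = 5, n_days = 4)
#' epochs <- simulate_actigraphy(truth, participant_id = "p1", seed = 1)
#' bins <- aggregate_5min(epochs)
#' fit <- fit_extended_cosine(bins)
#' fit$acrophase
#' @export
fit_extended_cosine <- function(data, min_obs = 576L) {
  stopifnot(all(c("time", "activity") %in% names(data)))
  keep <- !is.na(data$activity)
  t <- data$time[keep]
  y <- data$activity[keep]
  n <- length(y)
  if (n < min_obs) {
    abort(sprintf("Too few non-missing bins for a cosine fit: %d < %d.", n, min_obs))
  }

  rss_null <- sum((y - mean(y))^2)
  q <- quantile(y, c(0.05, 0.95), names = FALSE)
  min0 <- q[1]
  amp0 <- max(q[2] - q[1], 1e-6)

  lower <- c(minimum = 0, amplitude = 0, acrophase = -Inf, alpha = -0.99, beta = 0.1)
  upper <- c(minimum = Inf, amplitude = Inf, acrophase = Inf, alpha = 0.99, beta = 50)
  resid_fun <- function(p) {
    y - extended_cosine_curve(t, p[1], p[2], p[3], p[4], p[5])
  }

  best <- NULL
  best_rss <- Inf
  any_converged <- FALSE
  for (acr0 in seq(0, 22, by = 2)) {
    for (alpha0 in c(-0.6, 0, 0.6)) {
      start <- c(minimum = min0, amplitude = amp0, acrophase = acr0,
                 alpha = alpha0, beta = 2)
      res <- tryCatch(
        minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                           fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 300, ftol = 1e-12, ptol = 1e-10)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      rss <- res$deviance
      ok <- res$info %in% 1:4
      any_converged <- any_converged || ok
      if (rss < best_rss) {
        best_rss <- rss
        best <- res
      }
    }
  }
  if (is.null(best)) abort("Extended cosine optimization failed from every start.")

  p <- best$par
  # Report the curve's own peak/nadir: for the symmetric anti-logistic link
  # the peak sits at the acrophase parameter, but we take the argmax on a
  # 1-minute grid (earliest on ties) so the report holds by construction.
  grid <- seq(0, 24 - 1 / 60, by = 1 / 60)
  curve <- extended_cosine_curve(grid, p[1], p[2], p[3], p[4], p[5])
  peak_t <- grid[which.max(curve)]
  amp_hat <- max(curve) - min(curve)
  min_hat <- min(curve)

  extended_cosine_fit(
    minimum = min_hat, amplitude = amp_hat, acrophase = peak_t,
    alpha = unname(p[4]), beta = unname(p[5]),
    rss = best_rss, rss_null = rss_null, n_obs = n,
    converged = any_converged && best$info %in% 1:4
  )
}

#' Fit the extended cosine model for every participant in a bin table
#'
#' @param bins Output of [aggregate_5min()] for one or more participants
#'   (columns `participant_id`, `time`, `activity`).
#' @param min_obs Passed to [fit_extended_cosine()].
#' @return A tibble with one row per participant: the seven parametric
#'   columns (`pseudo_F`, `amplitude`, `mesor`, `amp_mesor_ratio`,
#'   `acrophase`, `alpha`, `beta`) plus `minimum`, `n_obs` and `converged`.
#'   Participants whose fit errors (e.g. too few bins) are dropped with a
#'   warning.
#' @export
fit_cosine_by_participant <- function(bins, min_obs = 576L) {
  bins |>
    dplyr::group_by(.data$participant_id) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fit = purrr::map(.data$data, function(d) {
        tryCatch(fit_extended_cosine(d, min_obs = min_obs),
                 error = function(e) {
                   warn(sprintf("Cosine fit failed: %s", conditionMessage(e)))
                   NULL
                 })
      })
    ) |>
    dplyr::filter(!purrr::map_lgl(.data$fit, is.null)) |>
    dplyr::mutate(par = purrr::map(.data$fit, tidy_fit_row)) |>
    dplyr::select("participant_id", "par") |>
    tidyr::unnest("par")
}

tidy_fit_row <- function(fit) {
  tibble::tibble(
    pseudo_F = fit$pseudo_F, amplitude = fit$amplitude, mesor = fit$mesor,
    amp_mesor_ratio = fit$amp_mesor_ratio, acrophase = fit$acrophase,
    minimum = fit$minimum, alpha = fit$alpha, beta = fit$beta,
    n_obs = fit$n_obs, converged = fit$converged
  )
}
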