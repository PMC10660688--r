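# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn .env
#' @importFrom stats coef pchisq pnorm qnorm quantile rbinom rlnorm rnorm runif
#'   sd var weighted.mean predict deviance df.residual vcov setNames
#'   complete.cases as.formula
NULL

# Weighted quantile of type-2 flavour: the weighted empirical CDF is cut at
# probability p; at an exact jump the two adjacent order statistics are
# averaged. Reduces to stats::quantile(type = 2) under equal weights.
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), all(is.finite(x)))
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p - 1e-12)[1L]
    if (cw[i] <= p + 1e-12 && i < length(x)) {
      (x[i] + x[i + 1L]) / 2
    } else {
      x[i]
    }
  }, numeric(1))
}

# Circular helpers on the 24-h clock -----------------------------------------

hours_to_angle <- function(h) h * 2 * pi / 24
angle_to_hours <- function(a) (a * 24 / (2 * pi)) %% 24

# Shortest distance between two clock times, in hours (range [0, 12]).
circular_distance_hours <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

# Circular median: the observed value minimizing total circular distance to
# the sample. Ties broken to the earliest clock time.
circular_median_hours <- function(h) {
  h <- h[!is.na(h)]
  tot <- vapply(h, function(m) sum(circular_distance_hours(h, m)), numeric(1))
  sort(h[tot <= min(tot) + 1e-12])[1L]
}

# Circular standard deviation sqrt(-2 log Rbar), converted to hours.
circular_sd_hours <- function(h) {
  h <- h[!is.na(h)]
  a <- hours_to_angle(h)
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  rbar <- min(rbar, 1)
  sqrt(-2 * log(rbar)) * 24 / (2 * pi)
}

# Deterministic per-participant seed stream: large odd multiplier modulo
# 2^31 - 1 keeps streams distinct and reproducible under any iteration order.
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m + 7919 * (as.numeric(index) %% m)) %% m)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
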