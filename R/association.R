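# Survey-weighted model battery: logistic regression on abnormality flags,
# linear regression on log biomarker levels, proportional-odds ordinal
# regression on the abnormal composite, quintile trend tests, interaction
# tests, stratified runs and the shift-worker sensitivity variant.
#
# Weights enter the estimating equations as frequency-type weights
# (normalized to mean 1 so likelihood-scale statistics are calibrated);
# standard errors are robust (HC0 sandwich). This reproduces a
# weights-only survey analysis; no design strata/PSU information is used.

#' Covariate adjustment sets for the model battery
#'
#' Model 1 adjusts for age and gender; model 2 (the main model) adds race
#' and ethnicity, education, household income, marital status, smoking,
#' alcohol consumption and hepatitis B/C/E status; model 3 adds diabetes to
#' model 2 and model 4 adds BMI category to model 2. The behavioral
#' sensitivity set adds total activity and sleep duration to model 2.
#'
#' @return Named list of covariate-column vectors.
#' @export
adjustment_sets <- function() {
  m1 <- c("age", "gender")
  m2 <- c(m1, "race", "education", "income", "marital", "smoking", "alcohol",
          "hepatitis_b", "hepatitis_c", "hepatitis_e")
  list(
    model1 = m1,
    model2 = m2,
    model3 = c(m2, "diabetes"),
    model4 = c(m2, "bmi_cat"),
    sensitivity_behavior = c(m2, "total_activity", "sleep_minutes_per_day")
  )
}

# Build the analysis frame: complete cases on everything the model touches,
# exposure releveled so `reference` is the baseline, weights normalized to
# mean 1.
prepare_model_frame <- function(data, outcome, exposure, covariates,
                                weights_col, reference) {
  need <- c(outcome, exposure, covariates, weights_col)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Missing model columns: %s", paste(missing_cols, collapse = ", ")))
  }
  d <- data[, unique(need), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (!nrow(d)) abort("No complete cases for this model.")
  if (any(d[[weights_col]] <= 0)) abort("Weights must be positive.")
  d$.w <- d[[weights_col]] / mean(d[[weights_col]])
  lev <- sort(unique(d[[exposure]]))
  if (length(lev) < 2) abort("Exposure is constant: nothing to contrast.")
  if (!reference %in% lev) {
    abort(sprintf("Reference level %s absent from exposure `%s`.",
                  reference, exposure))
  }
  d$.exposure <- factor(d[[exposure]], levels = c(reference, setdiff(lev, reference)))
  d
}

# The formula environment must be the caller's frame so that model-frame
# machinery (weights lookup, sandwich refits) resolves objects there.
model_formula <- function(lhs, covariates, env = parent.frame()) {
  rhs <- paste(c(".exposure", covariates), collapse = " + ")
  as.formula(paste(lhs, "~", rhs), env = env)
}

# HC0 sandwich CI/p for a fitted glm/lm, restricted to exposure terms.
sandwich_terms <- function(fit, level_names, exponentiate) {
  V <- sandwich::vcovHC(fit, type = "HC0")
  cf <- coef(fit)
  keep <- grep("^\\.exposure", names(cf))
  est <- cf[keep]
  se <- sqrt(diag(V))[keep]
  z <- est / se
  tibble::tibble(
    level = sub("^\\.exposure", "", names(cf)[keep]),
    estimate = unname(if (exponentiate) exp(est) else est),
    conf.low = unname(if (exponentiate) exp(est - 1.96 * se) else est - 1.96 * se),
    conf.high = unname(if (exponentiate) exp(est + 1.96 * se) else est + 1.96 * se),
    std.error = unname(se),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

# Per-exposure-level counts and weighted outcome prevalence.
level_summaries <- function(d, outcome) {
  d |>
    dplyr::group_by(level = as.character(.data$.exposure)) |>
    dplyr::summarise(
      n = dplyr::n(),
      weighted_pct = 100 * weighted.mean(as.numeric(.data[[outcome]]), .data$.w),
      .groups = "drop"
    )
}

new_association_result <- function(tbl, outcome, exposure, model_label, fit,
                                   n_used) {
  structure(
    tbl,
    outcome = outcome, exposure = exposure, model = model_label,
    n_used = n_used, fit = fit,
    class = c("rar_association", class(tbl))
  )
}

#' Survey-weighted logistic regression for one exposure-outcome pair
#'
#' Fits a weighted logistic model of a binary abnormality outcome on
#' exposure-quintile indicator contrasts (against the configured reference
#' quintile) plus covariates. Weights act as frequency-type weights in the
#' estimating equations; standard errors are HC0 sandwich; ORs are
#' `exp(coef)` with 95% CIs `exp(coef +/- 1.96 SE)`. Possible
#' quasi-separation (fitted probabilities at 0/1 or extreme coefficients) is
#' flagged in a `separation` column rather than silently diverging.
#'
#' @param data Scored participant table.
#' @param outcome Name of a logical/0-1 outcome column.
#' @param exposure Name of the quintile (or score) column.
#' @param covariates Character vector of adjustment columns (see
#'   [adjustment_sets()]).
#' @param weights_col Survey-weight column.
#' @param reference Reference exposure level (default 5, i.e. Q5).
#' @param model_label Free-text label carried into the result.
#' @return A `rar_association` tibble: one row per non-reference level with
#'   `n`, `weighted_pct`, OR (`estimate`), `conf.low`, `conf.high`,
#'   `p.value`, plus a reference row with OR 1.
#' @export
fit_weighted_logistic <- function(data, outcome, exposure,
                                  covariates = character(),
                                  weights_col = "weight", reference = 5,
                                  model_label = "custom") {
  d <- prepare_model_frame(data, outcome, exposure, covariates,
                           weights_col, reference)
  d$.y <- as.numeric(d[[outcome]])
  fit <- glm(model_formula(".y", covariates), data = d,
             family = stats::quasibinomial(), weights = d$.w)
  sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) ||
    any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  if (sep) warn("Possible quasi-separation: estimates flagged, interpret with care.")
  terms <- sandwich_terms(fit, levels(d$.exposure), exponentiate = TRUE)
  ref_row <- tibble::tibble(level = levels(d$.exposure)[1], estimate = 1,
                            conf.low = NA_real_, conf.high = NA_real_,
                            std.error = NA_real_, p.value = NA_real_)
  tbl <- dplyr::bind_rows(ref_row, terms) |>
    dplyr::left_join(level_summaries(d, ".y"), by = "level") |>
    dplyr::mutate(reference = .data$level == ref_row$level[1],
                  separation = sep)
  new_association_result(tbl, outcome, exposure, model_label, fit, nrow(d))
}

#' Survey-weighted linear regression on log biomarker levels
#'
#' Natural-log-transforms a strictly positive biomarker level and fits
#' weighted least squares with HC0 sandwich standard errors; coefficients
#' are per-quintile differences in mean log level versus the reference.
#'
#' @inheritParams fit_weighted_logistic
#' @param outcome Name of a strictly positive level column.
#' @return A `rar_association` tibble of betas with CIs (not
#'   exponentiated).
#' @export
fit_weighted_linear_log <- function(data, outcome, exposure,
                                    covariates = character(),
                                    weights_col = "weight", reference = 5,
                                    model_label = "custom") {
  d <- prepare_model_frame(data, outcome, exposure, covariates,
                           weights_col, reference)
  if (any(d[[outcome]] <= 0)) {
    abort(sprintf("`%s` must be strictly positive to log-transform.", outcome))
  }
  d$.y <- log(d[[outcome]])
  fit <- stats::lm(model_formula(".y", covariates), data = d, weights = d$.w)
  terms <- sandwich_terms(fit, levels(d$.exposure), exponentiate = FALSE)
  ref_row <- tibble::tibble(level = levels(d$.exposure)[1], estimate = 0,
                            conf.low = NA_real_, conf.high = NA_real_,
                            std.error = NA_real_, p.value = NA_real_)
  tbl <- dplyr::bind_rows(ref_row, terms) |>
    dplyr::left_join(
      d |>
        dplyr::group_by(level = as.character(.data$.exposure)) |>
        dplyr::summarise(n = dplyr::n(), .groups = "drop"),
      by = "level"
    ) |>
    dplyr::mutate(reference = .data$level == ref_row$level[1])
  new_association_result(tbl, outcome, exposure, model_label, fit, nrow(d))
}

#' Survey-weighted proportional-odds model for the abnormal composite
#'
#' Fits a weighted ordinal (proportional-odds) logistic regression of the
#' 0/1/2/3+ abnormal-biomarker composite on exposure contrasts plus
#' covariates, with sandwich standard errors. Outcome levels absent from
#' the data are collapsed with a warning.
#'
#' @inheritParams fit_weighted_logistic
#' @param outcome Name of the ordered composite column (integer 0-3).
#' @return A `rar_association` tibble of common ORs across cut-points.
#' @export
fit_ordinal_logistic <- function(data, outcome, exposure,
                                 covariates = character(),
                                 weights_col = "weight", reference = 5,
                                 model_label = "custom") {
  d <- prepare_model_frame(data, outcome, exposure, covariates,
                           weights_col, reference)
  y <- factor(d[[outcome]], levels = sort(unique(d[[outcome]])), ordered = TRUE)
  if (nlevels(y) < length(unique(0:3))) {
    warn("Some composite levels are absent; remaining levels are used as-is.")
  }
  if (nlevels(y) < 2) abort("Composite outcome has a single level.")
  if (nlevels(y) == 2L) {
    # a two-level ordinal model IS a binary logistic model
    warn("Composite has two levels; fitting the equivalent binary logistic model.")
    data2 <- data
    data2$.bin <- as.numeric(data2[[outcome]] == max(as.numeric(as.character(y))))
    return(fit_weighted_logistic(data2, ".bin", exposure, covariates,
                                 weights_col, reference, model_label))
  }
  d$.y <- y
  # polr's internal start-value glm warns about non-integer successes under
  # frequency-type weights; that is expected and harmless here
  fit <- withCallingHandlers(
    MASS::polr(model_formula(".y", covariates), data = d,
               weights = d$.w, Hess = TRUE),
    warning = function(w) {
      if (grepl("non-integer #successes", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  V <- sandwich::sandwich(fit)
  cf <- coef(fit) # regression coefficients only (no zeta cut-points)
  keep <- grep("^\\.exposure", names(cf))
  se <- sqrt(diag(V))[names(cf)[keep]]
  z <- cf[keep] / se
  terms <- tibble::tibble(
    level = sub("^\\.exposure", "", names(cf)[keep]),
    estimate = unname(exp(cf[keep])),
    conf.low = unname(exp(cf[keep] - 1.96 * se)),
    conf.high = unname(exp(cf[keep] + 1.96 * se)),
    std.error = unname(se),
    p.value = unname(2 * pnorm(-abs(z)))
  )
  ref_row <- tibble::tibble(level = levels(d$.exposure)[1], estimate = 1,
                            conf.low = NA_real_, conf.high = NA_real_,
                            std.error = NA_real_, p.value = NA_real_)
  tbl <- dplyr::bind_rows(ref_row, terms) |>
    dplyr::left_join(
      d |>
        dplyr::group_by(level = as.character(.data$.exposure)) |>
        dplyr::summarise(n = dplyr::n(), .groups = "drop"),
      by = "level"
    ) |>
    dplyr::mutate(reference = .data$level == ref_row$level[1])
  new_association_result(tbl, outcome, exposure, model_label, fit, nrow(d))
}

#' Wald trend test across exposure quintiles
#'
#' Refits the model with the quintile index entered as a single continuous
#' covariate and returns the Wald p-value (HC0 sandwich SE) for its
#' coefficient. The p-value is invariant to affine recoding of the index.
#'
#' @inheritParams fit_weighted_logistic
#' @param family `"logistic"` (binary outcome) or `"linear_log"` (positive
#'   level, log-transformed).
#' @return A one-row tibble: `estimate` (per-quintile log-OR or log-level
#'   slope), `std.error`, `p.value`.
#' @export
trend_test <- function(data, outcome, exposure, covariates = character(),
                       weights_col = "weight",
                       family = c("logistic", "linear_log")) {
  family <- match.arg(family)
  need <- c(outcome, exposure, covariates, weights_col)
  d <- data[, unique(need), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (length(unique(d[[exposure]])) < 2) abort("Exposure is constant: trend undefined.")
  d$.w <- d[[weights_col]] / mean(d[[weights_col]])
  d$.trend <- as.numeric(d[[exposure]])
  rhs <- paste(c(".trend", covariates), collapse = " + ")
  if (family == "logistic") {
    d$.y <- as.numeric(d[[outcome]])
    fit <- glm(as.formula(paste(".y ~", rhs)), data = d,
               family = stats::quasibinomial(), weights = d$.w)
  } else {
    if (any(d[[outcome]] <= 0)) abort("Levels must be positive to log-transform.")
    d$.y <- log(d[[outcome]])
    fit <- stats::lm(as.formula(paste(".y ~", rhs)), data = d, weights = d$.w)
  }
  se <- sqrt(diag(sandwich::vcovHC(fit, type = "HC0")))[".trend"]
  est <- coef(fit)[".trend"]
  tibble::tibble(estimate = unname(est), std.error = unname(se),
                 p.value = unname(2 * pnorm(-abs(est / se))))
}

#' Working likelihood-ratio test for effect modification
#'
#' Compares weighted fits with and without exposure-by-modifier
#' cross-product terms. Under frequency-type weights the drop in weighted
#' deviance is a working (pseudo-likelihood) LRT whose null distribution is
#' inflated by a factor of about `E[w^2]/E[w]^2` when weights are unrelated
#' to the outcome; a first-order Rao-Scott-style correction divides the
#' statistic by the mean squared normalized weight before referring it to
#' the chi-squared distribution. With equal weights the factor is exactly 1
#' and the ordinary LRT is recovered.
#'
#' @inheritParams fit_weighted_logistic
#' @param modifier Name of the effect-modifier column (e.g. alcohol, BMI
#'   category, diabetes, exam session).
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @export
interaction_test <- function(data, outcome, exposure, modifier,
                             covariates = character(),
                             weights_col = "weight", reference = 5) {
  if (length(unique(stats::na.omit(data[[modifier]]))) < 2) {
    abort(sprintf("Modifier `%s` is constant.", modifier))
  }
  d <- prepare_model_frame(data, outcome, exposure,
                           unique(c(covariates, modifier)),
                           weights_col, reference)
  d$.y <- as.numeric(d[[outcome]])
  base_rhs <- paste(c(".exposure", unique(c(covariates, modifier))),
                    collapse = " + ")
  f0 <- as.formula(paste(".y ~", base_rhs))
  f1 <- as.formula(paste(".y ~", base_rhs,
                         sprintf("+ .exposure:%s", modifier)))
  fit0 <- glm(f0, data = d, family = stats::quasibinomial(), weights = d$.w)
  fit1 <- glm(f1, data = d, family = stats::quasibinomial(), weights = d$.w)
  # per-cell event check: a modifier level with no events makes the
  # cross-product terms unstable
  cells <- table(d$.exposure[d$.y == 1], d[[modifier]][d$.y == 1])
  if (any(cells == 0)) {
    warn("A modifier level has an exposure cell with zero events; interaction test may be unstable.")
  }
  stat <- max(deviance(fit0) - deviance(fit1), 0)
  df <- df.residual(fit0) - df.residual(fit1)
  if (df <= 0) abort("Interaction terms are aliased; no testable cross-product.")
  # design-effect correction: with weights unrelated to the outcome the
  # working LRT is inflated by ~E[w^2] (weights normalized to mean 1)
  stat_adj <- stat / mean(d$.w^2)
  tibble::tibble(statistic = stat_adj, df = df,
                 p.value = pchisq(stat_adj, df, lower.tail = FALSE))
}

#' Fit a model within each stratum of a covariate
#'
#' @inheritParams fit_weighted_logistic
#' @param strata Name of the stratifying column.
#' @return A tibble of per-stratum association rows, with a
#'   `small_stratum` flag when any exposure-by-outcome cell holds fewer
#'   than 5 events. Empty or failing strata are skipped with a warning.
#' @export
stratified_run <- function(data, outcome, exposure, strata,
                           covariates = character(), weights_col = "weight",
                           reference = 5) {
  out <- list()
  for (s in sort(unique(stats::na.omit(data[[strata]])))) {
    d <- data[!is.na(data[[strata]]) & data[[strata]] == s, , drop = FALSE]
    if (!nrow(d)) {
      warn(sprintf("Stratum %s=%s is empty; skipped.", strata, s))
      next
    }
    res <- tryCatch(
      fit_weighted_logistic(d, outcome, exposure, covariates, weights_col,
                            reference, model_label = sprintf("%s=%s", strata, s)),
      error = function(e) {
        warn(sprintf("Stratum %s=%s failed: %s", strata, s, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) next
    events <- table(d[[exposure]][as.logical(d[[outcome]])])
    res$small_stratum <- length(events) == 0 || any(events < 5) ||
      length(events) < length(unique(d[[exposure]]))
    res$stratum <- as.character(s)
    out <- c(out, list(tibble::as_tibble(res)))
  }
  dplyr::bind_rows(out)
}

#' Sensitivity analysis excluding flagged shift workers
#'
#' Refits the model after removing participants flagged by
#' [flag_shift_workers()] (night-shift work / unconventional sleep timing).
#'
#' @inheritParams fit_weighted_logistic
#' @param flags Logical vector aligned with `data` rows.
#' @return A `rar_association` with attribute `n_removed`.
#' @export
sensitivity_exclude_shift <- function(data, flags, outcome, exposure,
                                      covariates = character(),
                                      weights_col = "weight", reference = 5) {
  stopifnot(length(flags) == nrow(data))
  keep <- !flags | is.na(flags)
  if (!any(keep)) abort("Every participant is flagged: empty analysis set.")
  res <- fit_weighted_logistic(data[keep, , drop = FALSE], outcome, exposure,
                               covariates, weights_col, reference,
                               model_label = "excluding shift workers")
  attr(res, "n_removed") <- sum(!keep)
  res
}
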