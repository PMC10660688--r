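#' Run the full association battery
#'
#' For every RAR parameter's quintiles crossed with every binary abnormality
#' outcome and every requested adjustment model, fits the weighted logistic
#' model (reference quintile per [reference_quintiles()]) plus the Wald
#' trend test, and — optionally — the ordinal composite analyses and the
#' shift-worker sensitivity refits. Per-cell failures are recorded and the
#' run continues.
#'
#' @param data Scored analytic table ([score_participants()] output joined
#'   with covariates and weights).
#' @param exposures RAR parameters to analyse (default all seven).
#' @param outcomes Binary outcome columns (default the six `abnormal_*`
#'   flags present in `data`).
#' @param models Adjustment sets from [adjustment_sets()] to run.
#' @param weights_col Survey-weight column.
#' @param composite Also fit the proportional-odds model of
#'   `abnormal_composite` on each exposure (main model only)?
#' @param shift_flags Optional logical vector for the shift-worker
#'   sensitivity refit (main model only).
#' @return A list of tibbles: `results` (one row per exposure x outcome x
#'   model x quintile with OR, CI, p, n, weighted %, and the model's trend
#'   p), `composite` (ordinal ORs, when requested), `sensitivity`
#'   (shift-worker exclusion refits, when flags given) and `failures`.
#' @export
run_full_analysis <- function(data,
                              exposures = intersect(RAR_PARAMETERS, names(data)),
                              outcomes = NULL,
                              models = c("model1", "model2", "model3", "model4"),
                              weights_col = "weight",
                              composite = FALSE,
                              shift_flags = NULL) {
  sets <- adjustment_sets()
  bad <- setdiff(models, names(sets))
  if (length(bad)) abort(sprintf("Unknown model set: %s", paste(bad, collapse = ", ")))
  if (is.null(outcomes)) {
    outcomes <- intersect(paste0("abnormal_", BIOMARKERS), names(data))
  }
  refs <- reference_quintiles()

  results <- list()
  failures <- list()
  for (exp_par in exposures) {
    qcol <- paste0("quintile_", exp_par)
    if (!qcol %in% names(data)) {
      failures <- c(failures, list(tibble::tibble(
        exposure = exp_par, outcome = NA_character_, model = NA_character_,
        error = sprintf("missing quintile column `%s`", qcol))))
      next
    }
    ref <- refs[[exp_par]]
    for (out_col in outcomes) {
      for (m in models) {
        covs <- intersect(sets[[m]], names(data))
        cell <- tryCatch({
          fit <- fit_weighted_logistic(data, out_col, qcol, covs,
                                       weights_col, ref, model_label = m)
          tr <- trend_test(data, out_col, qcol, covs, weights_col, "logistic")
          tibble::as_tibble(fit) |>
            dplyr::mutate(exposure = exp_par, outcome = out_col, model = m,
                          p_trend = tr$p.value)
        }, error = function(e) {
          failures <<- c(failures, list(tibble::tibble(
            exposure = exp_par, outcome = out_col, model = m,
            error = conditionMessage(e))))
          NULL
        })
        if (!is.null(cell)) results <- c(results, list(cell))
      }
    }
  }

  comp <- NULL
  if (composite && "abnormal_composite" %in% names(data)) {
    comp_rows <- list()
    for (exp_par in exposures) {
      qcol <- paste0("quintile_", exp_par)
      if (!qcol %in% names(data)) next
      cell <- tryCatch(
        fit_ordinal_logistic(data, "abnormal_composite", qcol,
                             intersect(sets$model2, names(data)),
                             weights_col, refs[[exp_par]],
                             model_label = "model2") |>
          tibble::as_tibble() |>
          dplyr::mutate(exposure = exp_par, outcome = "abnormal_composite",
                        model = "model2"),
        error = function(e) {
          failures <<- c(failures, list(tibble::tibble(
            exposure = exp_par, outcome = "abnormal_composite",
            model = "model2", error = conditionMessage(e))))
          NULL
        }
      )
      if (!is.null(cell)) comp_rows <- c(comp_rows, list(cell))
    }
    comp <- dplyr::bind_rows(comp_rows)
  }

  sens <- NULL
  if (!is.null(shift_flags)) {
    sens_rows <- list()
    for (out_col in outcomes) {
      cell <- tryCatch(
        sensitivity_exclude_shift(data, shift_flags, out_col,
                                  "quintile_pseudo_F",
                                  intersect(sets$model2, names(data)),
                                  weights_col, refs[["pseudo_F"]]) |>
          tibble::as_tibble() |>
          dplyr::mutate(exposure = "pseudo_F", outcome = out_col,
                        model = "model2_no_shift"),
        error = function(e) NULL
      )
      if (!is.null(cell)) sens_rows <- c(sens_rows, list(cell))
    }
    sens <- dplyr::bind_rows(sens_rows)
  }

  list(results = dplyr::bind_rows(results),
       composite = comp,
       sensitivity = sens,
       failures = dplyr::bind_rows(failures))
}

#' End-to-end pipeline from epoch records to scored participants
#'
#' Convenience chain: quality filtering, 5-minute binning, extended cosine
#' fits, non-parametric metrics and behavioral covariates, joined into one
#' participant table ready for [score_participants()] and
#' [run_full_analysis()].
#'
#' @param epochs Minute-epoch records ([read_epochs()] layout).
#' @param min_obs Minimum non-missing bins for the cosine fit.
#' @return A tibble per retained participant: the seven RAR parameters plus
#'   `sleep_minutes_per_day` and `total_activity`.
#' @export
derive_rhythms <- function(epochs, min_obs = 576L) {
  day_flags <- classify_valid_days(epochs)
  bins <- aggregate_5min(epochs, day_flags)
  par_tab <- fit_cosine_by_participant(bins, min_obs = min_obs)
  np <- nonparametric_by_participant(bins)
  beh <- behavioral_covariates(epochs, day_flags)
  par_tab |>
    dplyr::left_join(np, by = "participant_id") |>
    dplyr::left_join(beh, by = "participant_id")
}
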