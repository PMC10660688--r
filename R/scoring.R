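# Quintile scoring: survey-weighted quintile assignment for the seven RAR
# parameters, the impaired-rhythmicity composite, and the sex-specific
# liver-biomarker abnormality flags with their 0-3+ composite.

# The seven RAR parameters and the quintile presumed lowest-risk for each:
# Q1 for acrophase and IV, Q5 for the other five.
RAR_PARAMETERS <- c("pseudo_F", "amplitude", "mesor", "amp_mesor_ratio",
                    "acrophase", "IS", "IV")

#' Reference quintile per RAR parameter
#'
#' The reference (presumed lowest-risk) quintile is Q1 for acrophase and IV
#' and Q5 for the five remaining parameters.
#'
#' @return Named integer vector over the seven parameters.
#' @export
reference_quintiles <- function() {
  setNames(c(5L, 5L, 5L, 5L, 1L, 5L, 1L), RAR_PARAMETERS)
}

#' Survey-weighted quintile assignment
#'
#' Cut-points are the weighted 20/40/60/80th percentiles (weighted type-2
#' percentile: the weighted CDF is cut at each probability, averaging
#' adjacent values at exact jumps). Values equal to a cut-point go to the
#' lower quintile, so labels are invariant under strictly monotone
#' transforms of the values. With unit weights each quintile holds ~20% of
#' the weight, absent heavy ties.
#'
#' @param values Numeric vector (`NA` allowed, propagated).
#' @param weights Positive weights (default equal).
#' @return A list: `quintile` (integer 1-5, 1 = lowest values) and
#'   `cut_points` (the four percentile cut-offs).
#' @export
assign_quintiles <- function(values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values))
  if (any(weights[!is.na(values)] <= 0)) abort("Weights must be positive.")
  ok <- !is.na(values)
  if (length(unique(values[ok])) < 5L) {
    abort("Quintile assignment needs at least 5 distinct values.")
  }
  cuts <- weighted_quantile(values[ok], weights[ok], c(0.2, 0.4, 0.6, 0.8))
  q <- rep(NA_integer_, length(values))
  q[ok] <- 1L + rowSums(outer(values[ok], cuts, `>`))
  list(quintile = q, cut_points = cuts)
}

#' Impaired-rhythmicity composite score
#'
#' Counts how many of four parametric rhythm measures sit in their
#' least-healthy quintile — Q1 for the F statistic, amplitude and mesor, Q5
#' for acrophase — capped at 3 ("3+"). 0 represents robust rhythmicity, 3+
#' the most impaired.
#'
#' @param q_f,q_amplitude,q_mesor,q_acrophase Integer quintile labels (1-5).
#' @return Integer score in `{0, 1, 2, 3}` (3 read as "3+"); `NA` if any
#'   quintile is missing.
#' @export
impaired_rhythmicity_score <- function(q_f, q_amplitude, q_mesor, q_acrophase) {
  score <- (q_f == 1L) + (q_amplitude == 1L) + (q_mesor == 1L) +
    (q_acrophase == 5L)
  pmin(as.integer(score), 3L)
}

#' Sex-specific liver-biomarker abnormality flags
#'
#' Applies the clinical cut-offs with strict inequalities: ALT > 47 IU/L in
#' men / > 30 in women; AST > 33 IU/L; ALP > 113 IU/L; GGT > 65 IU/L in men
#' / > 36 in women; albumin < 3.7 g/dL; bilirubin > 1.3 mg/dL.
#'
#' @param panel Data frame with columns `sex` (`"male"`/`"female"`) and the
#'   six level columns `alt`, `ast`, `alp`, `ggt`, `albumin`, `bilirubin`.
#' @return The input with `abnormal_*` logical columns (`NA` level gives
#'   `NA` flag) replaced/added.
#' @export
abnormal_flags <- function(panel) {
  need <- c("sex", BIOMARKERS)
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    abort(sprintf("Panel is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  lv <- as.matrix(panel[, BIOMARKERS])
  if (any(lv < 0, na.rm = TRUE)) abort("Negative biomarker levels are not allowed.")
  thr <- liver_thresholds()
  male <- panel$sex == "male"
  for (i in seq_len(nrow(thr))) {
    bm <- thr$biomarker[i]
    cut <- ifelse(male, thr$male[i], thr$female[i])
    panel[[paste0("abnormal_", bm)]] <- if (thr$direction[i] == "above") {
      panel[[bm]] > cut
    } else {
      panel[[bm]] < cut
    }
  }
  panel
}

#' Abnormal-biomarker composite score
#'
#' The number of abnormal liver-function markers (enzymes, albumin,
#' bilirubin) observed, capped at 3 ("3+").
#'
#' @param panel Data frame with the six `abnormal_*` logical columns.
#' @return Integer vector in `{0, 1, 2, 3}`; `NA` when every flag is
#'   missing. Markers with a missing flag simply do not count.
#' @export
abnormal_composite <- function(panel) {
  flags <- as.matrix(panel[, paste0("abnormal_", BIOMARKERS)])
  all_na <- rowSums(!is.na(flags)) == 0L
  score <- pmin(rowSums(flags, na.rm = TRUE), 3L)
  score[all_na] <- NA_integer_
  as.integer(score)
}

#' Score a participant table: RAR quintiles and both composites
#'
#' Assigns survey-weighted quintiles for each of the seven RAR parameters,
#' derives the impaired-rhythmicity score, and (when biomarker levels are
#' present) the abnormality flags and the abnormal composite.
#'
#' @param data Participant table carrying the RAR parameter columns
#'   (`pseudo_F`, `amplitude`, `mesor`, `amp_mesor_ratio`, `acrophase`,
#'   `IS`, `IV`), optionally `sex` plus the six biomarker level columns, and
#'   a weight column.
#' @param weights_col Name of the survey-weight column; `NULL` for
#'   unweighted quintiles (sensitivity option).
#' @return The input plus `quintile_*` columns, `impaired_score`, and — when
#'   a biomarker panel is present — `abnormal_*` and `abnormal_composite`.
#' @export
score_participants <- function(data, weights_col = "weight") {
  w <- if (is.null(weights_col)) rep(1, nrow(data)) else data[[weights_col]]
  for (p in intersect(RAR_PARAMETERS, names(data))) {
    data[[paste0("quintile_", p)]] <- assign_quintiles(data[[p]], w)$quintile
  }
  need_q <- paste0("quintile_", c("pseudo_F", "amplitude", "mesor", "acrophase"))
  if (all(need_q %in% names(data))) {
    data$impaired_score <- impaired_rhythmicity_score(
      data[[need_q[1]]], data[[need_q[2]]], data[[need_q[3]]], data[[need_q[4]]]
    )
  }
  if (all(c("sex", BIOMARKERS) %in% names(data))) {
    data <- abnormal_flags(data)
    data$abnormal_composite <- abnormal_composite(data)
  }
  data
}
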