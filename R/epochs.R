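# Minute-epoch actigraphy handling: readers for the package CSV dialect and
# NHANES-style SAS-transport minute files, the valid-day / valid-participant
# quality filters, aggregation to 5-minute bins, and the behavioral
# covariates (sleep duration, total activity) used downstream.

EPOCH_STATES <- c("wake", "sleep", "nonwear", "unknown")

# Normalize raw state codes: integers follow the NHANES minute-file
# convention (1 wake, 2 sleep, 3 nonwear); anything unrecognized -> unknown.
normalize_state <- function(x) {
  if (is.numeric(x)) {
    out <- c("wake", "sleep", "nonwear")[match(x, 1:3)]
  } else {
    x <- tolower(as.character(x))
    x[x %in% c("non-wear", "non_wear")] <- "nonwear"
    out <- ifelse(x %in% EPOCH_STATES, x, NA_character_)
  }
  out[is.na(out)] <- "unknown"
  out
}

validate_epochs <- function(df) {
  key <- paste(df$participant_id, df$day_index, df$minute_of_day)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    abort(sprintf("Duplicated epoch key (participant day minute): %s", dup[1]))
  }
  if (any(df$minute_of_day < 0 | df$minute_of_day > 1439)) {
    abort("`minute_of_day` must lie in [0, 1439].")
  }
  if (any(!is.na(df$activity) & df$activity < 0)) {
    abort("Negative activity values are not allowed.")
  }
  df
}

#' Read minute-epoch actigraphy records
#'
#' Supports two dialects that yield identical epoch streams: the package CSV
#' dialect (columns `participant_id`, `day_index`, `minute_of_day`,
#' `activity`, `state`) and NHANES-style SAS-transport minute files
#' (`SEQN`, `PAXDAYM`, `PAXSSNMP` or `PAXMINUTE`, `PAXMTSM`, `PAXPREDM`),
#' where the MIMS triaxial value becomes `activity` and the predicted state
#' code (1 wake, 2 sleep, 3 non-wear) is mapped onto the state enum.
#' Unrecognized state codes map to `unknown`; duplicated (participant, day,
#' minute) keys are an error naming the key.
#'
#' @param source Path to the file.
#' @param dialect `"csv"` or `"xpt"`.
#' @return A tibble of epoch records.
#' @export
read_epochs <- function(source, dialect = c("csv", "xpt")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    raw <- tryCatch(
      readr::read_csv(source, show_col_types = FALSE, progress = FALSE),
      error = function(e) abort(sprintf("Cannot parse '%s': %s", source,
                                        conditionMessage(e)))
    )
    need <- c("participant_id", "day_index", "minute_of_day", "activity", "state")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols)) {
      abort(sprintf("CSV dialect is missing columns: %s",
                    paste(missing_cols, collapse = ", ")))
    }
    prob <- readr::problems(raw)
    if (nrow(prob)) {
      abort(sprintf("Unparseable CSV content at row %d of '%s'.",
                    prob$row[1], source))
    }
    df <- tibble::tibble(
      participant_id = as.character(raw$participant_id),
      day_index = as.integer(raw$day_index),
      minute_of_day = as.integer(raw$minute_of_day),
      activity = as.numeric(raw$activity),
      state = normalize_state(raw$state)
    )
  } else {
    raw <- foreign::read.xport(source)
    names(raw) <- toupper(names(raw))
    minute_col <- intersect(c("PAXMINUTE", "PAXSSNMP"), names(raw))[1]
    need <- c("SEQN", "PAXDAYM", "PAXMTSM", "PAXPREDM")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) || is.na(minute_col)) {
      abort("XPT minute file lacks the expected SEQN/PAXDAYM/minute/PAXMTSM/PAXPREDM columns.")
    }
    df <- tibble::tibble(
      participant_id = as.character(raw$SEQN),
      day_index = as.integer(raw$PAXDAYM),
      minute_of_day = as.integer(raw[[minute_col]]),
      activity = as.numeric(raw$PAXMTSM),
      state = normalize_state(raw$PAXPREDM)
    )
    # NHANES codes missing MIMS as a negative sentinel
    df$activity[df$activity < 0] <- NA_real_
  }
  validate_epochs(df)
}

#' Write epoch records in the package CSV dialect
#'
#' @param epochs A tibble of epoch records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  readr::write_csv(epochs[, c("participant_id", "day_index", "minute_of_day",
                              "activity", "state")], path, progress = FALSE)
  invisible(path)
}

#' Flag valid measurement days
#'
#' A valid day has at least 20 h (1200 minutes) of wake plus sleep data;
#' non-wear, unknown and absent minutes do not count. Partial first/last
#' days are screened automatically by the same rule.
#'
#' @param epochs Epoch records for one or more participants.
#' @return A tibble with one row per (participant, day): `wear_minutes`
#'   (wake + sleep count) and `valid`.
#' @export
classify_valid_days <- function(epochs) {
  epochs |>
    dplyr::group_by(.data$participant_id, .data$day_index) |>
    dplyr::summarise(
      wear_minutes = sum(.data$state %in% c("wake", "sleep")),
      .groups = "drop"
    ) |>
    dplyr::mutate(valid = .data$wear_minutes >= 1200L)
}

#' Select participants with enough valid days
#'
#' Retains participants with at least 4 valid days of measurement.
#'
#' @param day_flags Output of [classify_valid_days()].
#' @param min_valid_days Retention threshold (default 4).
#' @return A tibble per participant: `n_valid_days`, `retained`.
#' @export
select_participants <- function(day_flags, min_valid_days = 4L) {
  day_flags |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_valid_days = sum(.data$valid), .groups = "drop") |>
    dplyr::mutate(retained = .data$n_valid_days >= min_valid_days)
}

# Restrict an epoch stream to its valid days; errors if the result would
# violate the >= 4 valid-day rule for any participant kept.
filter_valid <- function(epochs, day_flags = NULL, min_valid_days = 4L) {
  if (is.null(day_flags)) day_flags <- classify_valid_days(epochs)
  keep <- day_flags |> dplyr::filter(.data$valid)
  eligible <- select_participants(day_flags, min_valid_days) |>
    dplyr::filter(.data$retained)
  epochs |>
    dplyr::semi_join(keep, by = c("participant_id", "day_index")) |>
    dplyr::semi_join(eligible, by = "participant_id")
}

#' Aggregate valid-day epochs to 5-minute bin means
#'
#' Bins are anchored at midnight and half-open (`[5b, 5b + 5)` minutes).
#' Only wake and sleep minutes with a non-missing activity value enter the
#' mean; a bin with no usable minute is missing. Only valid days of
#' participants with at least 4 valid days are binned.
#'
#' @param epochs Epoch records.
#' @param day_flags Optional precomputed [classify_valid_days()] output.
#' @return A tibble per (participant, day, bin): `bin` (0-287),
#'   `minute_of_day` (bin start), `time` (hours since the participant's
#'   first midnight, evaluated at the bin centre so a bin mean lines up
#'   with the curve value it estimates), and `activity` (bin mean).
#' @export
aggregate_5min <- function(epochs, day_flags = NULL) {
  filter_valid(epochs, day_flags) |>
    dplyr::mutate(
      bin = .data$minute_of_day %/% 5L,
      usable = .data$state %in% c("wake", "sleep") & !is.na(.data$activity)
    ) |>
    dplyr::group_by(.data$participant_id, .data$day_index, .data$bin) |>
    dplyr::summarise(
      activity = if (any(.data$usable)) {
        mean(.data$activity[.data$usable])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      minute_of_day = .data$bin * 5L,
      time = (.data$day_index - 1) * 24 + (.data$minute_of_day + 2.5) / 60
    )
}

#' Behavioral covariates from valid-day actigraphy
#'
#' Sleep duration is the mean over valid days of minutes labelled `sleep`;
#' total activity is the mean over valid days of the summed activity across
#' wake and sleep minutes (a daily total, averaged across days).
#'
#' @param epochs Epoch records.
#' @param day_flags Optional precomputed [classify_valid_days()] output.
#' @return A tibble per participant: `sleep_minutes_per_day`,
#'   `total_activity`.
#' @export
behavioral_covariates <- function(epochs, day_flags = NULL) {
  filter_valid(epochs, day_flags) |>
    dplyr::group_by(.data$participant_id, .data$day_index) |>
    dplyr::summarise(
      sleep_minutes = sum(.data$state == "sleep"),
      day_activity = sum(.data$activity[.data$state %in% c("wake", "sleep")],
                         na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      sleep_minutes_per_day = mean(.data$sleep_minutes),
      total_activity = mean(.data$day_activity),
      .groups = "drop"
    )
}
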