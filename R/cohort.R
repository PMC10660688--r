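# Eligibility cascade: sequential exclusions with an auditable ledger,
# mirroring a STROBE-style participant flow.

# Stage predicates in cascade order; each returns TRUE when the row is
# EXCLUDED at that stage. Ages of 80+ are excluded both because analyses
# target adults under 80 and because top-coded ages (everyone older coded as
# 80) hide the exact age.
exclusion_stages <- function() {
  list(
    list(label = "age < 20",
         cols = "age", drop = function(d) d$age < 20),
    list(label = "age >= 80 (top-coded)",
         cols = "age", drop = function(d) d$age >= 80),
    list(label = "pregnant",
         cols = "pregnant", drop = function(d) d$pregnant),
    list(label = "no actigraphy data",
         cols = "has_actigraphy", drop = function(d) !d$has_actigraphy),
    list(label = "< 4 valid actigraphy days",
         cols = "n_valid_days", drop = function(d) d$n_valid_days < 4),
    list(label = "no liver biomarker measures",
         cols = "has_biomarkers", drop = function(d) !d$has_biomarkers)
  )
}

#' Apply the eligibility exclusion cascade
#'
#' Sequentially drops participants aged under 20, aged 80 or older
#' (top-coded ages), pregnant, without actigraphy data, with fewer than 4
#' valid actigraphy days, and without any liver biomarker measure — in that
#' order — recording per-stage counts in an exclusion ledger. The final set
#' equals the intersection of all inclusion predicates; only the
#' attribution of an exclusion to a stage depends on the order.
#'
#' @param data Participant table with columns `age`, `pregnant`,
#'   `has_actigraphy`, `n_valid_days`, `has_biomarkers`.
#' @return A list: `data` (the analytic table) and `ledger` (a tibble of
#'   class `exclusion_ledger`: `stage`, `excluded`, `remaining`).
#' @export
apply_exclusions <- function(data) {
  stages <- exclusion_stages()
  for (st in stages) {
    if (!all(st$cols %in% names(data))) {
      abort(sprintf("Exclusion cascade requires column `%s`.", st$cols))
    }
  }
  rows <- list(tibble::tibble(stage = "assessed", excluded = 0L,
                              remaining = nrow(data)))
  for (st in stages) {
    drop <- st$drop(data)
    drop[is.na(drop)] <- FALSE
    data <- data[!drop, , drop = FALSE]
    rows <- c(rows, list(tibble::tibble(stage = st$label,
                                        excluded = sum(drop),
                                        remaining = nrow(data))))
  }
  ledger <- dplyr::bind_rows(rows)
  class(ledger) <- c("exclusion_ledger", class(ledger))
  list(data = data, ledger = validate_ledger(ledger))
}

validate_ledger <- function(ledger) {
  if (nrow(ledger) == 0) return(ledger)
  if (any(ledger$excluded < 0) || any(ledger$remaining < 0)) {
    abort("Ledger counts must be non-negative.")
  }
  if (nrow(ledger) > 1) {
    prev <- ledger$remaining[-nrow(ledger)]
    if (!all(ledger$remaining[-1] == prev - ledger$excluded[-1])) {
      abort("Ledger is arithmetically inconsistent: remaining_k must equal remaining_{k-1} - excluded_k.")
    }
  }
  ledger
}

#' Build an exclusion ledger from printed stage counts
#'
#' Reconstructs the cascade arithmetic from a baseline count and per-stage
#' excluded counts (e.g. counts transcribed from a published participant
#' flow), validating that the stages chain consistently.
#'
#' @param baseline Number assessed before any exclusion.
#' @param excluded Named integer vector of per-stage excluded counts, in
#'   cascade order.
#' @return An `exclusion_ledger` tibble.
#' @export
ledger_from_counts <- function(baseline, excluded) {
  remaining <- baseline - cumsum(c(0L, unname(excluded)))
  ledger <- tibble::tibble(
    stage = c("assessed", names(excluded)),
    excluded = c(0L, as.integer(excluded)),
    remaining = as.integer(remaining)
  )
  class(ledger) <- c("exclusion_ledger", class(ledger))
  validate_ledger(ledger)
}

#' Format an exclusion ledger as a participant-flow summary
#'
#' @param ledger An `exclusion_ledger`.
#' @return A character vector of report lines (also usable with
#'   `writeLines()`); the ledger itself is a tibble ready for `write_csv()`.
#' @export
ledger_report <- function(ledger) {
  validate_ledger(ledger)
  lines <- "Participant flow"
  if (nrow(ledger) == 0) return(lines)
  for (i in seq_len(nrow(ledger))) {
    lines <- c(lines, if (ledger$stage[i] == "assessed") {
      sprintf("  assessed: %d", ledger$remaining[i])
    } else {
      sprintf("  excluded %s: %d (remaining %d)",
              ledger$stage[i], ledger$excluded[i], ledger$remaining[i])
    })
  }
  c(lines, sprintf("  final analytic sample: %d",
                   ledger$remaining[nrow(ledger)]))
}
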