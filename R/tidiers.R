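# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an extended cosine fit into a parameter table
#'
#' @param x An `extended_cosine_fit`.
#' @param ... Unused.
#' @return A tibble with one row per curve parameter (`minimum`,
#'   `amplitude`, `acrophase`, `alpha`, `beta`, and the derived `mesor` and
#'   `amp_mesor_ratio`).
#' @method tidy extended_cosine_fit
#' @export
tidy.extended_cosine_fit <- function(x, ...) {
  tibble::tibble(
    term = c("minimum", "amplitude", "acrophase", "alpha", "beta",
             "mesor", "amp_mesor_ratio"),
    estimate = c(x$minimum, x$amplitude, x$acrophase, x$alpha, x$beta,
                 x$mesor, x$amp_mesor_ratio)
  )
}

#' One-row fit summary of an extended cosine fit
#'
#' @param x An `extended_cosine_fit`.
#' @param ... Unused.
#' @return A tibble: `pseudo_F`, `rss`, `rss_null`, `n_obs`, `converged`.
#' @method glance extended_cosine_fit
#' @export
glance.extended_cosine_fit <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, rss = x$rss, rss_null = x$rss_null,
                 n_obs = x$n_obs, converged = x$converged)
}

#' Tidy an association result
#'
#' `rar_association` objects already are tibbles; `tidy()` strips the
#' attributes and adds the identifying columns.
#'
#' @param x A `rar_association`.
#' @param ... Unused.
#' @return A plain tibble with `outcome`, `exposure` and `model` columns.
#' @method tidy rar_association
#' @export
tidy.rar_association <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(outcome = attr(x, "outcome"),
                  exposure = attr(x, "exposure"),
                  model = attr(x, "model"))
}

#' One-row summary of an association result
#'
#' @param x A `rar_association`.
#' @param ... Unused.
#' @return A tibble: `outcome`, `exposure`, `model`, `n_used`.
#' @method glance rar_association
#' @export
glance.rar_association <- function(x, ...) {
  tibble::tibble(outcome = attr(x, "outcome"), exposure = attr(x, "exposure"),
                 model = attr(x, "model"), n_used = attr(x, "n_used"))
}

#' Plot a fitted extended cosine curve over the observed profile
#'
#' @param object An `extended_cosine_fit`.
#' @param bins Optional bin table (columns `time`, `activity`) to show the
#'   observed 24-h average profile behind the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot extended_cosine_fit
#' @export
autoplot.extended_cosine_fit <- function(object, bins = NULL, ...) {
  grid <- tibble::tibble(time = seq(0, 24, by = 1 / 12))
  grid$activity <- predict(object, grid$time)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$time, y = .data$activity))
  if (!is.null(bins)) {
    prof <- bins |>
      dplyr::mutate(tod = .data$time %% 24) |>
      dplyr::group_by(.data$tod) |>
      dplyr::summarise(activity = mean(.data$activity, na.rm = TRUE),
                       .groups = "drop")
    p <- p + ggplot2::geom_point(
      data = prof, ggplot2::aes(x = .data$tod, y = .data$activity),
      colour = "grey55", size = 0.8
    )
  }
  p +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = object$acrophase, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Clock time (h)", y = "Activity",
                  title = sprintf("Extended cosine fit (pseudo-F %.1f)",
                                  object$pseudo_F)) +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios across exposure quintiles
#'
#' @param object A `rar_association`.
#' @param ... Unused.
#' @return A ggplot with the OR (log scale) and 95% CI per quintile.
#' @method autoplot rar_association
#' @export
autoplot.rar_association <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$level <- factor(d$level, levels = sort(unique(as.numeric(d$level))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Exposure quintile", y = "OR (95% CI)",
                  title = sprintf("%s ~ %s (%s)", attr(object, "outcome"),
                                  attr(object, "exposure"),
                                  attr(object, "model"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the 24-h average activity profile of one participant
#'
#' @param bins [aggregate_5min()] output for one participant.
#' @return A ggplot of the across-day average 5-minute profile.
#' @export
plot_activity_profile <- function(bins) {
  prof <- bins |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(activity = mean(.data$activity, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(hour = .data$bin * 5 / 60)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$hour, y = .data$activity)) +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Clock time (h)", y = "Mean activity") +
    ggplot2::theme_minimal()
}
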