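#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a detection model
#'
#' @param x A `detection_model`.
#' @param ... Unused.
#' @return One row per coefficient (`term`, `estimate`), in the broom
#'   style; standard errors are included when the model was fitted from
#'   data.
#' @method tidy detection_model
#' @export
tidy.detection_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    tibble::tibble(term = c("intercept", "slope"),
                   estimate = unname(s[, "Estimate"]),
                   std_error = unname(s[, "Std. Error"]))
  } else {
    tibble::tibble(term = c("intercept", "slope"),
                   estimate = c(x$intercept, x$slope),
                   std_error = NA_real_)
  }
}

#' One-row summary of a detection model
#'
#' @param x A `detection_model`.
#' @param ... Unused.
#' @return A tibble with `slope`, `intercept`, `r_squared`, `n_points`.
#' @method glance detection_model
#' @export
glance.detection_model <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_points = x$n_points)
}

#' Per-category shares of an efficiency report
#'
#' @param x An `efficiency_report`.
#' @param ... Unused.
#' @return A tibble with one row per outcome category: clone count,
#'   observed share and (when a detection model was applied) corrected
#'   share.
#' @method tidy efficiency_report
#' @export
tidy.efficiency_report <- function(x, ...) x$shares

#' One-row summary of an efficiency report
#'
#' @param x An `efficiency_report`.
#' @param ... Unused.
#' @return A tibble with the headline efficiency statistics.
#' @method glance efficiency_report
#' @export
glance.efficiency_report <- function(x, ...) {
  tibble::tibble(
    total_clones = x$total_clones,
    observed_success_fraction = x$observed_success_fraction,
    corrected_success_fraction = x$corrected_success_fraction,
    absolute_rod_rate_uncorrected = x$absolute_rod_rate_uncorrected,
    absolute_rod_rate_corrected = x$absolute_rod_rate_corrected,
    relative_success_among_edited = x$relative_success_among_edited,
    rod_fraction = x$rod_fraction)
}

#' Plot a fitted detection model over its mixture series
#'
#' Observed versus true percent Success with the fitted regression line
#' and the identity line for reference.
#'
#' @param object A `detection_model` (fitted via [fit_detection_model()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot detection_model
#' @export
autoplot.detection_model <- function(object, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "true Success (%)", y = "observed Success (%)",
                  subtitle = sprintf("slope %.3f, intercept %.3f, r² %.3f",
                                     object$slope, object$intercept,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    p <- p + ggplot2::geom_point(
      data = object$fit$model,
      ggplot2::aes(x = .data$true_pct, y = .data$observed_pct))
  }
  p
}

#' Stacked outcome-category bar chart of a clone count table
#'
#' @param object A `clone_count_table` from [classify_set()] (tables from
#'   several samples can be row-bound first).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clone_count_table
#' @export
autoplot.clone_count_table <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$share,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "clones", fill = "outcome") +
    ggplot2::theme_minimal()
}

#' Observed versus corrected category shares of an efficiency report
#'
#' @param object An `efficiency_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot efficiency_report
#' @export
autoplot.efficiency_report <- function(object, ...) {
  d <- object$shares |>
    tidyr::pivot_longer(dplyr::ends_with("_share"),
                        names_to = "kind", values_to = "share") |>
    dplyr::mutate(kind = sub("_share$", "", .data$kind))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$share,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "share of clones", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
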