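#' Plot a stimulus trajectory
#'
#' Path of the stimulus centre through the field, coloured by time.
#'
#' @param trajectory A [simulate_trajectory()] tibble (or any tibble with
#'   `sx`, `sy`).
#' @param half_width Field half-width for the frame, degrees.
#' @return A ggplot.
#' @export
plot_trajectory <- function(trajectory, half_width = 3) {
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = .data$sx, y = .data$sy,
                               colour = dplyr::row_number(.data$sx))) +
    ggplot2::geom_path(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::coord_fixed(xlim = c(-half_width, half_width),
                         ylim = c(-half_width, half_width)) +
    ggplot2::labs(x = "horizontal position (deg)",
                  y = "vertical position (deg)") +
    ggplot2::theme_minimal()
}

#' Plot fitted receptive-field centres
#'
#' @param fits A `prf_fits` tibble (optionally with an `area` column to
#'   facet by).
#' @param half_width Span-field half-width for the frame, degrees.
#' @return A ggplot; point size tracks fitted sigma.
#' @export
plot_rf_centers <- function(fits, half_width = 3.8) {
  p <- ggplot2::ggplot(fits,
                       ggplot2::aes(x = .data$mu_x, y = .data$mu_y,
                                    size = .data$sigma)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::coord_fixed(xlim = c(-half_width, half_width),
                         ylim = c(-half_width, half_width)) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "RF centre x (deg)", y = "RF centre y (deg)",
                  size = "sigma (deg)") +
    ggplot2::theme_minimal()
  if ("area" %in% names(fits)) p <- p + ggplot2::facet_wrap(~area)
  p
}

#' Plot per-area decoding accuracy
#'
#' Mean accuracy per area and axis with t-based confidence intervals across
#' subjects when several subjects are present.
#'
#' @param accuracy A tibble with columns `area`, `r_horizontal`,
#'   `r_vertical` (and optionally `subject`, `method`).
#' @return A ggplot.
#' @export
plot_accuracy_by_area <- function(accuracy) {
  long <- tidyr::pivot_longer(accuracy,
                              cols = c("r_horizontal", "r_vertical"),
                              names_to = "axis", values_to = "r") |>
    dplyr::mutate(axis = sub("^r_", "", .data$axis),
                  area = factor(.data$area, levels = unique(.data$area)))
  grp <- c("area", "axis", intersect("method", names(long)))
  summ <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      mean_r = mean(.data$r),
      ci_low = if (dplyr::n() >= 2) ci_across_subjects(.data$r)$ci_low
               else NA_real_,
      ci_high = if (dplyr::n() >= 2) ci_across_subjects(.data$r)$ci_high
                else NA_real_,
      .groups = "drop"
    )
  p <- ggplot2::ggplot(summ,
                       ggplot2::aes(x = .data$area, y = .data$mean_r,
                                    colour = .data$axis,
                                    group = .data$axis)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "prediction accuracy (r)") +
    ggplot2::theme_minimal()
  if ("method" %in% names(summ)) p <- p + ggplot2::facet_wrap(~method)
  p
}

#' Plot distance-exclusion accuracy curves
#'
#' @param curves A tibble from [distance_exclusion_curve()], optionally with
#'   an `area` (or other grouping) column.
#' @param colour Optional name of the grouping column to colour by.
#' @return A ggplot.
#' @export
plot_decay_curves <- function(curves, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data$threshold, y = .data$r_horizontal)
  } else {
    ggplot2::aes(x = .data$threshold, y = .data$r_horizontal,
                 colour = .data[[colour]], group = .data[[colour]])
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "exclusion threshold (deg)",
                  y = "horizontal accuracy (r)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a decay fit
#'
#' Observed accuracy-vs-threshold points with the fitted exponential decay.
#'
#' @param object A `"decay_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  dd <- seq(min(object$data$threshold), max(object$data$threshold),
            length.out = 100)
  fit <- tibble::tibble(
    threshold = dd,
    accuracy = object$amplitude * exp(-dd / object$tau) + object$baseline
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$threshold, y = .data$accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit, colour = "steelblue") +
    ggplot2::labs(x = "exclusion threshold (deg)",
                  y = "horizontal accuracy (r)",
                  subtitle = sprintf("tau = %.2f deg", object$tau)) +
    ggplot2::theme_minimal()
}

#' Autoplot a decoded trajectory
#'
#' True and predicted coordinates over volumes, per axis.
#'
#' @param object A `decoded_trajectory` tibble.
#' @param n_volumes Show at most this many volumes from the start.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decoded_trajectory
#' @export
autoplot.decoded_trajectory <- function(object, n_volumes = 200, ...) {
  d <- utils::head(object, n_volumes)
  long <- dplyr::bind_rows(
    tibble::tibble(volume = d$volume, axis = "horizontal",
                   true = d$true_x, predicted = d$pred_x),
    tibble::tibble(volume = d$volume, axis = "vertical",
                   true = d$true_y, predicted = d$pred_y)
  ) |>
    tidyr::pivot_longer(c("true", "predicted"), names_to = "which",
                        values_to = "position")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$volume, y = .data$position,
                                     colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "fMRI volume", y = "position (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}
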