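#' Plot a band-ratio series
#'
#' Ratio trajectories per band (and per source if several) over window
#' start time.
#'
#' @param ratios Tidy band-ratio tibble from [sliding_band_ratios()],
#'   [eeg_band_ratios()] or [eye_band_ratios()].
#' @return A ggplot object.
#' @export
plot_band_ratios <- function(ratios) {
  p <- ggplot2::ggplot(ratios,
                       ggplot2::aes(x = .data$window_start_s,
                                    y = .data$ratio,
                                    colour = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start (s)", y = "relative band power",
                  colour = "band") +
    ggplot2::theme_minimal()
  if (length(unique(ratios$source)) > 1) {
    p <- p + ggplot2::facet_wrap(~source)
  }
  p
}

#' Plot held-out predictions of a synchronization fit
#'
#' Overlays the predicted EEG band-ratio trajectory on the observed one
#' across the held-out windows.
#'
#' @param object A `sync_fit` from [fit_sync()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sync_fit
#' @export
autoplot.sync_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$predictions, c("y", "y_pred"),
                           names_to = "series", values_to = "value")
  d$series <- ifelse(d$series == "y", "observed", "predicted")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_start_s,
                                  y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sprintf("%s: held-out R2 = %.3f", object$spec$model,
                      object$metrics$r2),
      x = "window start (s)", y = "EEG band ratio", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of condition comparisons
#'
#' Mean R-squared with +/- 1 sd error bars per condition for each
#' triple, faceted by quadrant, significance marks where p < 0.05.
#'
#' @param comparisons Output of [compare_sync()].
#' @param retained_only Plot only retained triples (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparisons, retained_only = FALSE) {
  d <- comparisons
  if (retained_only) d <- d[d$retained, ]
  d$triple <- paste(d$eye_feature, d$channel, d$band)
  long <- dplyr::bind_rows(
    tibble::tibble(triple = d$triple, quadrant = d$quadrant,
                   condition = "empathic", mean = d$mean_emp,
                   std = d$std_emp, sig = d$significance),
    tibble::tibble(triple = d$triple, quadrant = d$quadrant,
                   condition = "non-empathic", mean = d$mean_non,
                   std = d$std_non, sig = ""))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$triple, y = .data$mean,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$std,
                   ymax = .data$mean + .data$std),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig,
                                    y = .data$mean + .data$std),
                       vjust = -0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~quadrant, scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(R^2), fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
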