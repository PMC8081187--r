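#' Tidy a CSP model
#'
#' One row per spatial filter with its class-A variance-ratio eigenvalue
#' and whether it is among the selected extremes.
#'
#' @param x A [fit_csp()] model.
#' @param ... Unused.
#' @return A tibble with columns `filter`, `eigenvalue`, `selected`.
#' @export
tidy.csp_model <- function(x, ...) {
  tibble(filter = seq_len(x$n_channels), eigenvalue = x$eigenvalues,
         selected = seq_len(x$n_channels) %in% x$selected_idx)
}

#' @rdname tidy.csp_model
#' @export
glance.csp_model <- function(x, ...) {
  tibble(n_channels = x$n_channels, m = x$m,
         lambda_max = max(x$eigenvalues), lambda_min = min(x$eigenvalues))
}

#' Tidy cross-validation results
#'
#' @param x A [crossval()] report.
#' @param ... Unused.
#' @return `tidy()`: the per-fold accuracy tibble. `glance()`: a one-row
#'   summary.
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(mean_accuracy = x$mean, sd_accuracy = x$sd, k = x$k,
         classifier = x$classifier, m = x$m, seed = x$seed)
}

#' Tidy a grand-average ERP
#'
#' @param x A [grand_average()] summary.
#' @param ... Unused.
#' @return A long tibble: `channel`, `time_ms`, `mean`, `se`.
#' @export
tidy.erp_summary <- function(x, ...) {
  out <- tidyr::expand_grid(channel = x$channels, time_ms = x$times)
  out$mean <- as.vector(t(x$avg))
  out$se <- as.vector(t(x$se))
  out
}

#' Tidy a linear discriminant model
#'
#' @param x A [fit_lda()] model.
#' @param ... Unused.
#' @return A tibble of discriminant weights, one row per feature, plus
#'   the bias term.
#' @export
tidy.lda_model <- function(x, ...) {
  tibble(term = c(names(x$w) %||% paste0("x", seq_along(x$w)), "(bias)"),
         estimate = c(unname(x$w), x$bias))
}

#' Plot sliding-window decoding accuracy
#'
#' @param object A [sliding_window_eval()] report.
#' @param ... Unused.
#' @return A ggplot: accuracy vs window start, chance level dashed.
#' @export
autoplot.sliding_window_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_start,
                                       y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window start (ms after stimulus onset)",
                  y = "cross-validated accuracy",
                  title = paste0(attr(object, "win"), " ms sliding window, ",
                                 attr(object, "step"), " ms step")) +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Plot a grand-average ERP with its standard-error band
#'
#' @param object A [grand_average()] summary.
#' @param channels Channels to draw (default: first channel).
#' @param ... Unused.
#' @return A ggplot of mean +/- SE over time.
#' @export
autoplot.erp_summary <- function(object, channels = object$channels[1], ...) {
  df <- dplyr::filter(tidy(object), .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$mean,
                                   colour = .data$channel,
                                   fill = .data$channel)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time (ms)", y = "amplitude (µV)",
                  title = paste0("grand average (n = ", object$n, ", '",
                                 object$label, "')"))
}

#' Plot a time-frequency map (ERSP or ITC)
#'
#' @param object A [ersp()] or [itc()] result.
#' @param ... Unused.
#' @return A ggplot raster of the map.
#' @export
autoplot.timefreq_map <- function(object, ...) {
  kind <- attr(object, "kind")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$freq,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (identical(kind, "ERSP")) "dB" else kind) +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)", title = kind)
}

#' Plot per-band classification contributions
#'
#' @param contribution A [band_contribution()] table.
#' @return A ggplot bar chart with the chance level marked.
#' @export
plot_band_contribution <- function(contribution) {
  chance <- attr(contribution, "chance") %||% 0.5
  ggplot2::ggplot(contribution,
                  ggplot2::aes(x = .data$band, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$accuracy - .data$sd,
                                        ymax = .data$accuracy + .data$sd),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "cross-validated accuracy") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}
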