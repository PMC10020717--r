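#' Plot a hemodynamic profile
#'
#' Two stacked panels: cross-section averaged pressure (mmHg) and
#' segment-averaged WSS (Pa) along the centerline arc length, colored by
#' anatomical region.
#'
#' @param object a `hemodynamic_profile` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot hemodynamic_profile
#' @export
autoplot.hemodynamic_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("pressure_mmHg", "wss_Pa"),
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, c("pressure_mmHg", "wss_Pa"),
                         c("pressure [mmHg]", "WSS [Pa]"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s_mm, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4, color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$region), size = 0.8) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "centerline arc length [mm]", y = NULL,
                  color = "region") +
    ggplot2::theme_minimal()
}

#' Compare surrogate and reference profiles
#'
#' @param pred surrogate prediction tibble (`pressure_mmHg`, `wss_Pa`).
#' @param ref reference `hemodynamic_profile`.
#' @return a ggplot object.
#' @export
plot_profile_comparison <- function(pred, ref) {
  df <- dplyr::bind_rows(
    tibble(s_mm = ref$s_mm, pressure_mmHg = ref$pressure_mmHg,
           wss_Pa = ref$wss_Pa, method = "reference"),
    tibble(s_mm = ref$s_mm, pressure_mmHg = pred$pressure_mmHg,
           wss_Pa = pred$wss_Pa, method = "surrogate")
  )
  long <- tidyr::pivot_longer(df, c("pressure_mmHg", "wss_Pa"),
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, c("pressure_mmHg", "wss_Pa"),
                         c("pressure [mmHg]", "WSS [Pa]"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s_mm, y = .data$value,
                                     color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "centerline arc length [mm]", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity map
#'
#' Heatmap of the output pressure RMSE induced by local +/-1 SD feature
#' perturbations over centerline points.
#'
#' @param object a `sensitivity_map` tibble.
#' @param channel `"pressure"` or `"wss"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sensitivity_map
#' @export
autoplot.sensitivity_map <- function(object, channel = c("pressure", "wss"), ...) {
  channel <- match.arg(channel)
  val <- if (channel == "pressure") "drmse_p" else "drmse_wss"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$point, y = .data$feature,
                                       fill = .data[[val]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (channel == "pressure")
      "dRMSE [mmHg]" else "dRMSE [Pa]") +
    ggplot2::labs(x = "centerline point", y = "perturbed feature") +
    ggplot2::theme_minimal()
}

#' Scatter plots of case accuracy against severity
#'
#' Absolute pressure RMSE against reference MPD and WSS RMSE against peak
#' reference WSS, mirroring the standard accuracy-versus-severity view.
#'
#' @param metrics tibble of [case_metrics()] rows.
#' @return a ggplot object.
#' @export
plot_metrics <- function(metrics) {
  df <- dplyr::bind_rows(
    tibble(x = metrics$mpd_ref, y = metrics$rmse_p,
           panel = "pressure RMSE [mmHg] vs MPD [mmHg]"),
    tibble(x = metrics$peak_wss_ref, y = metrics$rmse_wss,
           panel = "WSS RMSE [Pa] vs peak WSS [Pa]")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
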