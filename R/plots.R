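#' Plot a recording's impedance channels and ICP
#'
#' Faceted impedance traces (usable samples only, by default) with the ICP
#' series as a final panel, on a common time axis in minutes.
#'
#' @param object A `bim_recording`.
#' @param usable_only Drop masked samples (default TRUE).
#' @param thin Keep every `thin`-th impedance sample for plotting speed
#'   (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bim_recording <- function(object, usable_only = TRUE, thin = 10,
                                   ...) {
  ch <- object$channels
  if (usable_only) ch <- ch[ch$quality, ]
  ch <- ch[seq(1, nrow(ch), by = max(1, thin)), ]
  ch$panel <- paste0("Z ch ", ch$channel)
  icp <- object$icp
  icp$panel <- "ICP"
  d <- dplyr::bind_rows(
    dplyr::transmute(ch, t_min = .data$t_s / 60, value = .data$z_ohm,
                     panel = .data$panel),
    dplyr::transmute(icp, t_min = .data$t_s / 60, value = .data$icp_mmhg,
                     panel = .data$panel))
  d$panel <- factor(d$panel, levels = c(paste0("Z ch ", 1:8), "ICP"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = "Impedance (ohm) / ICP (mmHg)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot cohort localization colour maps
#'
#' Tile map of the cohort mean normalized impedance change per element and
#' event, annotated with each event's threshold classification.
#'
#' @param object A `bim_localization`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bim_localization <- function(object, ...) {
  d <- tidy(object)
  d$lab <- paste0(d$phase, "\n", d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$channel), y = .data$lab,
                                  fill = .data$mean_ndz)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "mean nΔZ") +
    ggplot2::labs(x = "Element", y = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot per-step detection signals against the threshold
#'
#' Mean across-channel impedance change from the zero-volume reference at
#' each volume step, per subject, with the detection threshold.
#'
#' @param analysis A `bim_cohort_analysis` or `bim_metrics`.
#' @param phase Stepped phase (default `"inflation"`).
#' @param threshold_ohm Threshold line (default 7.1).
#' @return A ggplot object.
#' @export
plot_detection <- function(analysis, phase = "inflation",
                           threshold_ohm = 7.1) {
  if (inherits(analysis, "bim_metrics")) {
    st <- dplyr::mutate(analysis$steps, subject = "subject")
  } else {
    stop("plot_detection expects a bim_metrics object", call. = FALSE)
  }
  d <- st[st$phase == phase, ] |>
    dplyr::group_by(.data$volume_ml) |>
    dplyr::summarise(signal = mean(.data$z_vn - .data$z_v0, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$volume_ml, y = abs(.data$signal))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold_ohm, color = "red",
                        linetype = 2) +
    ggplot2::labs(x = "Volume (mL)", y = "|mean ΔZ| (ohm)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot an analysis of means
#'
#' Per-event mean standard deviation against the grand mean and decision
#' limits.
#'
#' @param object A `bim_anom`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bim_anom <- function(object, ...) {
  d <- object$limits
  ggplot2::ggplot(d, ggplot2::aes(x = .data$event, y = .data$mean_std)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$flagged), size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.2,
                           linetype = 3) +
    ggplot2::geom_hline(yintercept = object$grand_mean) +
    ggplot2::labs(x = NULL, y = "Mean std of ΔZ (ohm)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
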