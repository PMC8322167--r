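#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x A `bim_calibration`.
#' @param ... Unused.
#' @return Tibble with one row per term (`intercept`, `slope`).
#' @export
tidy.bim_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.bim_calibration
#' @export
glance.bim_calibration <- function(x, ...) {
  tibble::tibble(n = length(x$measured),
                 sigma = stats::sd(x$residuals),
                 max_abs_residual = max(abs(x$residuals)))
}

#' Tidy event metrics
#'
#' @param x A `bim_metrics`.
#' @param ... Unused.
#' @return The per-channel metrics tibble.
#' @export
tidy.bim_metrics <- function(x, ...) x$channels

#' Tidy a localization result
#'
#' @param x A `bim_localization`.
#' @param ... Unused.
#' @return The cohort mean-map tibble joined with each event's
#'   classification.
#' @export
tidy.bim_localization <- function(x, ...) {
  dplyr::left_join(x$maps, x$classification, by = "phase")
}

#' Tidy an analysis of means
#'
#' @param x A `bim_anom`.
#' @param ... Unused.
#' @return The decision-limit tibble.
#' @export
tidy.bim_anom <- function(x, ...) x$limits

#' @rdname tidy.bim_anom
#' @export
glance.bim_anom <- function(x, ...) {
  tibble::tibble(grand_mean = x$grand_mean, h = x$h, df = x$df,
                 s_pooled = x$s_pooled, alpha = x$alpha,
                 n_flagged = sum(x$limits$flagged))
}

#' Tidy a variance summary
#'
#' @param x A `bim_variance_summary`.
#' @param ... Unused.
#' @return The per subject-event variance tibble.
#' @export
tidy.bim_variance_summary <- function(x, ...) x$per_event

#' @rdname tidy.bim_variance_summary
#' @export
glance.bim_variance_summary <- function(x, ...) {
  tibble::tibble(levene_w = x$levene$statistic,
                 levene_p = x$levene$p_value,
                 welch_t = x$welch$statistic,
                 welch_df = x$welch$df,
                 welch_p = x$welch$p_value,
                 n_focal_greater = sum(x$within_subject$focal_greater,
                                       na.rm = TRUE),
                 n_subjects = nrow(x$within_subject))
}

#' One-row summary of a cohort analysis
#'
#' @param x A `bim_cohort_analysis`.
#' @param ... Unused.
#' @return One-row tibble with detection, discrimination, localization and
#'   variance-separation summaries.
#' @export
glance.bim_cohort_analysis <- function(x, ...) {
  di <- x$di_subject
  mean_di <- function(ph) {
    v <- di$mean_di[di$phase == ph]
    if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
  }
  cls <- x$localization$classification
  pick <- function(ph, col) {
    v <- cls[[col]][cls$phase == ph]
    if (length(v) == 0) NA else v
  }
  vg <- glance(x$variance)
  tibble::tibble(
    n_subjects = length(unique(x$metrics$subject)),
    n_detected = sum(x$detections$detected),
    mean_detection_volume_ml = mean(x$detections$detection_volume_ml,
                                    na.rm = TRUE),
    mean_di_inflation = mean_di("inflation"),
    mean_di_hematoma = mean_di("hematoma"),
    inflation_label = pick("inflation", "label"),
    inflation_element = pick("inflation", "element"),
    hematoma_label = pick("hematoma", "label"),
    hematoma_element = pick("hematoma", "element"),
    levene_p = vg$levene_p,
    welch_p = vg$welch_p,
    n_focal_greater = vg$n_focal_greater)
}

#' Export cohort metrics in long format for external modelling
#'
#' A tidy long table (one row per subject-event-channel impedance change)
#' suitable for refitting repeated-measures mixed models in any external
#' statistics package (subject as random effect, injury and element as fixed
#' effects).
#'
#' @param analysis A `bim_cohort_analysis`.
#' @param path Optional CSV path to write.
#' @return The long-format tibble, invisibly if written.
#' @export
export_long_format <- function(analysis, path = NULL) {
  out <- analysis$metrics |>
    dplyr::transmute(subject = .data$subject, injury = .data$phase,
                     element = .data$channel, delta_z_ohm = .data$delta_z,
                     delta_icp_mmhg = .data$delta_icp, di = .data$di)
  if (!is.null(path)) {
    readr::write_csv(out, path)
    return(invisible(out))
  }
  out
}
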