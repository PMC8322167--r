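#' Mask CT acquisition windows
#'
#' Active CT acquisition injects broadband noise into every impedance
#' channel; those samples are excluded before any event metric is computed.
#' Samples within `[t_ct - pad_s, t_ct + duration + pad_s]` of each `ct` sync
#' event are masked (quality set `FALSE`) on all channels. Sample values are
#' never altered: filtering is a mask-only contract.
#'
#' @param rec A `bim_recording` whose events include `ct` markers (none is a
#'   no-op).
#' @param pad_s Guard band either side of the burst, seconds (default 5).
#' @param default_duration_s Burst duration assumed when the event carries no
#'   `duration_s` (default 30).
#' @return The recording with an updated quality mask.
#' @export
flag_ct_windows <- function(rec, pad_s = 5, default_duration_s = 30) {
  ct <- rec$events[rec$events$label == "ct", ]
  if (nrow(ct) == 0) return(rec)
  dur <- ifelse(is.na(ct$duration_s), default_duration_s, ct$duration_s)
  t <- rec$channels$t_s
  masked <- rep(FALSE, length(t))
  for (i in seq_len(nrow(ct))) {
    masked <- masked | (t >= ct$t_s[i] - pad_s & t <= ct$t_s[i] + dur[i] + pad_s)
  }
  rec$channels$quality <- rec$channels$quality & !masked
  rec
}

#' Detect step (DC-shift) artifacts in one channel trace
#'
#' Electrical DC shifts and compromised electrodes appear as abrupt persistent
#' offsets. The detector compares medians of adjacent time windows and flags a
#' step where their difference exceeds `step_threshold_ohm` -- unless the step
#' is synchronous with a protocol volume step (within `sync_tol_s`),
#' since protocol-synchronous changes are signal, not artifact. Samples after
#' an unrepaired step are masked until the windowed median returns to within
#' the threshold of its pre-step level (a decaying droplet transient
#' recovers; a persistent DC shift stays masked to the end of the trace).
#'
#' Windowed medians (rather than derivatives) are robust to the 80 s
#' channel-multiplexing gaps.
#'
#' @param trace Tibble with `t_s`, `z_ohm`, `quality` for one channel.
#' @param window_s Median window length, seconds (default 60).
#' @param step_threshold_ohm Minimum |median difference| flagged (default 20).
#' @param step_times Protocol volume-step times, seconds (default none).
#' @param sync_tol_s Half-width of the protocol-synchrony exclusion window
#'   around each volume step, seconds (default: one detector window). A
#'   detected change this close to a volume step is attributed to the
#'   protocol, not to an artifact.
#' @return List with `detections` (tibble `t_s`, `magnitude_ohm`) and `trace`
#'   (quality updated: `FALSE` after the first detected step).
#' @export
detect_step_artifacts <- function(trace, window_s = 60,
                                  step_threshold_ohm = 20,
                                  step_times = numeric(),
                                  sync_tol_s = window_s) {
  use <- trace$quality & is.finite(trace$z_ohm)
  if (sum(use) < 2) {
    return(list(detections = tibble::tibble(t_s = numeric(),
                                            magnitude_ohm = numeric()),
                trace = trace))
  }
  t0 <- min(trace$t_s[use])
  win <- floor((trace$t_s - t0) / window_s)
  d <- trace[use, ]
  wid <- win[use]
  med <- tapply(d$z_ohm, wid, stats::median)
  wstart <- tapply(d$t_s, wid, min)
  if (length(med) < 2) {
    return(list(detections = tibble::tibble(t_s = numeric(),
                                            magnitude_ohm = numeric()),
                trace = trace))
  }
  dm <- diff(med)
  t_step <- wstart[-1]           # step lies before the later window
  hits <- abs(dm) > step_threshold_ohm
  if (length(step_times) > 0 && any(hits)) {
    sync <- vapply(t_step, function(ts) {
      any(abs(ts - step_times) <= sync_tol_s)
    }, logical(1))
    hits <- hits & !sync
  }
  hit_idx <- which(hits)             # position in the window sequence
  keep <- logical(length(hit_idx))
  masked_until <- -Inf
  for (j in seq_along(hit_idx)) {
    w <- hit_idx[j]                  # step between windows w and w + 1
    t_from <- unname(t_step[w])
    if (t_from <= masked_until) next # inside an earlier artifact's span
                                     # (boundary case: the recovery step)
    keep[j] <- TRUE
    m0 <- med[w]                     # pre-step level
    later <- seq(w + 1, length(med))
    rec_w <- later[abs(med[later] - m0) <= step_threshold_ohm]
    t_to <- if (length(rec_w) > 0) unname(wstart[rec_w[1]]) else Inf
    trace$quality <- trace$quality &
      !(trace$t_s >= t_from & trace$t_s < t_to)
    masked_until <- max(masked_until, t_to)
  }
  detections <- tibble::tibble(
    t_s = unname(t_step[hit_idx[keep]]),
    magnitude_ohm = unname(dm[hit_idx[keep]]))
  list(detections = detections, trace = trace)
}

#' Per-trace quality exclusion
#'
#' A channel-phase trace is excluded from downstream statistics when its
#' masked fraction exceeds `max_masked_fraction` or its detected unrepaired
#' step count exceeds `max_unrepaired_steps`. Every exclusion is reported
#' with its reason. All eight channels excluded for one phase is a pipeline
#' error ("phase unusable").
#'
#' @param rec A `bim_recording` with masks already computed (e.g. after
#'   [flag_ct_windows()] and [detect_step_artifacts()]).
#' @param protocol The `bim_protocol` defining phase windows.
#' @param step_detections Optional tibble `channel`, `t_s` of detected step
#'   artifacts (as from [preprocess_recording()]).
#' @param max_masked_fraction Default 0.5.
#' @param max_unrepaired_steps Default 1.
#' @return A tibble of class `bim_quality` with one row per channel-phase:
#'   `phase`, `channel`, `fraction_masked`, `n_steps`, `excluded`, `reason`.
#' @export
apply_quality_exclusion <- function(rec, protocol, step_detections = NULL,
                                    max_masked_fraction = 0.5,
                                    max_unrepaired_steps = 1) {
  ph <- protocol_phases(protocol)
  if (is.null(step_detections)) {
    step_detections <- tibble::tibble(channel = integer(), t_s = numeric())
  }
  ch <- rec$channels
  # one pass: per (phase, channel) sample and masked-sample counts
  p_idx <- findInterval(ch$t_s, ph$start_s)
  in_span <- p_idx >= 1 & ch$t_s < ph$end_s[pmin(p_idx, nrow(ph))]
  key <- p_idx[in_span] * 10 + ch$channel[in_span]
  n_tot <- rowsum(rep(1L, sum(in_span)), key)
  n_mask <- rowsum(as.integer(!ch$quality[in_span]), key)
  grid <- tidyr::expand_grid(phase_i = seq_len(nrow(ph)), channel = 1:8)
  gkey <- as.character(grid$phase_i * 10 + grid$channel)
  n_g <- n_tot[gkey, 1]; n_g[is.na(n_g)] <- 0
  m_g <- n_mask[gkey, 1]; m_g[is.na(m_g)] <- 0
  frac <- ifelse(n_g == 0, 1, m_g / pmax(n_g, 1))
  sp_idx <- findInterval(step_detections$t_s, ph$start_s)
  skey <- sp_idx * 10 + step_detections$channel
  n_steps <- vapply(as.numeric(gkey), function(k) sum(skey == k), integer(1))
  excluded <- frac > max_masked_fraction | n_steps > max_unrepaired_steps
  reason <- rep(NA_character_, nrow(grid))
  too_masked <- excluded & frac > max_masked_fraction
  reason[too_masked] <- sprintf("masked fraction %.2f > %.2f",
                                frac[too_masked], max_masked_fraction)
  too_steppy <- excluded & !too_masked
  reason[too_steppy] <- sprintf("%d unrepaired steps > %d",
                                n_steps[too_steppy], max_unrepaired_steps)
  report <- tibble::tibble(phase = ph$phase[grid$phase_i],
                           channel = grid$channel,
                           fraction_masked = unname(frac),
                           n_steps = unname(n_steps),
                           excluded = unname(excluded), reason = reason)
  bad <- report |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(all_out = all(.data$excluded)) |>
    dplyr::filter(.data$all_out)
  if (nrow(bad) > 0) {
    stop("phase unusable: all 8 channels excluded for ",
         paste(bad$phase, collapse = ", "), call. = FALSE)
  }
  class(report) <- c("bim_quality", class(report))
  report
}

#' De-trend a trace against its late-baseline linear fit
#'
#' Fits a least-squares line to the usable samples of `baseline_window`
#' (canonically the final 10 min of baseline) and subtracts the extrapolated
#' line over `apply_span`, isolating injury response from systemic drift such
#' as electrode settling. The fit is returned for audit.
#'
#' @param trace Tibble with `t_s`, `z_ohm`, `quality` for one channel.
#' @param baseline_window Numeric length-2, `c(start, end)` seconds.
#' @param apply_span Numeric length-2 span over which the line is subtracted
#'   (default: from `baseline_window[1]` to the end of the trace).
#' @return List with `trace` (de-trended), `slope` (ohm/s), `intercept`
#'   (ohm at t = 0).
#' @export
detrend_baseline <- function(trace, baseline_window,
                             apply_span = c(baseline_window[1],
                                            max(trace$t_s))) {
  in_bl <- trace$quality & is.finite(trace$z_ohm) &
    trace$t_s >= baseline_window[1] & trace$t_s <= baseline_window[2]
  if (sum(in_bl) < 2) {
    stop("baseline unusable; run without de-trending", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, trace$t_s[in_bl]), trace$z_ohm[in_bl])
  coefs <- fit$coefficients
  in_apply <- trace$t_s >= apply_span[1] & trace$t_s <= apply_span[2]
  trace$z_ohm[in_apply] <- trace$z_ohm[in_apply] -
    (coefs[1] + coefs[2] * trace$t_s[in_apply])
  list(trace = trace, slope = unname(coefs[2]), intercept = unname(coefs[1]))
}

#' De-trend all channels of a recording
#'
#' Applies [detrend_baseline()] per channel using the final
#' `baseline_fit_min` minutes of the protocol's baseline phase, subtracting
#' the extrapolated line from the start of the fit window through the end of
#' the recording, so the zero-volume reference window and every event share
#' one drift-corrected reference frame (mixing de-trended and raw spans
#' would corrupt later events' changes).
#'
#' @param rec A `bim_recording`.
#' @param protocol The `bim_protocol`.
#' @param baseline_fit_min Minutes of late baseline used for the fit
#'   (default 10).
#' @return List with `recording` (de-trended) and `fits` (tibble `channel`,
#'   `slope_ohm_per_s`, `intercept_ohm`).
#' @export
detrend_recording <- function(rec, protocol, baseline_fit_min = 10) {
  ph <- protocol_phases(protocol)
  bl_end <- ph$end_s[ph$phase == "baseline"]
  if (length(bl_end) == 0) stop("protocol has no baseline phase", call. = FALSE)
  window <- c(bl_end - baseline_fit_min * 60, bl_end)
  span_end <- max(ph$end_s)
  fits <- vector("list", 8)
  for (c_id in 1:8) {
    idx <- rec$channels$channel == c_id
    res <- detrend_baseline(rec$channels[idx, ], window,
                            apply_span = c(window[1], span_end))
    rec$channels[idx, ] <- res$trace
    fits[[c_id]] <- tibble::tibble(channel = c_id,
                                   slope_ohm_per_s = res$slope,
                                   intercept_ohm = res$intercept)
  }
  list(recording = rec, fits = dplyr::bind_rows(fits))
}

#' Run the full preprocessing chain
#'
#' CT-window masking, per-channel step-artifact detection (with protocol
#' step synchrony excluded), and per-trace quality exclusion.
#'
#' @param rec A `bim_recording`.
#' @param protocol The `bim_protocol`.
#' @param pad_s CT guard band, seconds.
#' @param window_s,step_threshold_ohm Step-detector parameters.
#' @param max_masked_fraction,max_unrepaired_steps Exclusion thresholds.
#' @return List with `recording` (masks updated), `quality` (the
#'   `bim_quality` report) and `step_detections`.
#' @export
preprocess_recording <- function(rec, protocol, pad_s = 5, window_s = 60,
                                 step_threshold_ohm = 20,
                                 max_masked_fraction = 0.5,
                                 max_unrepaired_steps = 1) {
  rec <- flag_ct_windows(rec, pad_s = pad_s)
  st <- protocol_steps(protocol)
  detections <- vector("list", 8)
  for (c_id in 1:8) {
    idx <- which(rec$channels$channel == c_id)
    res <- detect_step_artifacts(rec$channels[idx, ], window_s = window_s,
                                 step_threshold_ohm = step_threshold_ohm,
                                 step_times = st$t_s)
    rec$channels[idx, ] <- res$trace
    if (nrow(res$detections) > 0) {
      detections[[c_id]] <- dplyr::mutate(res$detections, channel = c_id,
                                          .before = 1)
    }
  }
  step_detections <- dplyr::bind_rows(detections)
  if (nrow(step_detections) == 0) {
    step_detections <- tibble::tibble(channel = integer(), t_s = numeric(),
                                      magnitude_ohm = numeric())
  }
  quality <- apply_quality_exclusion(rec, protocol,
                                     step_detections = step_detections,
                                     max_masked_fraction = max_masked_fraction,
                                     max_unrepaired_steps = max_unrepaired_steps)
  list(recording = rec, quality = quality, step_detections = step_detections)
}
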