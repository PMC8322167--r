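#' Zero-volume impedance of a channel
#'
#' The reference impedance of an event: the mean of the usable samples in the
#' 80 s immediately preceding the event start. Eighty seconds is one full
#' multiplexing cycle, so each channel contributes exactly its one active
#' 10 s slot.
#'
#' @param trace Tibble with `t_s`, `z_ohm`, `quality` for one channel.
#' @param event_start_s Event (e.g. inflation) start time, seconds.
#' @param window_s Reference window length before the event (default 80).
#' @return Mean impedance in ohms, or `NA` if no usable sample lies in the
#'   window (the channel is unusable for this event).
#' @export
zero_volume_impedance <- function(trace, event_start_s, window_s = 80) {
  use <- trace$quality & is.finite(trace$z_ohm) &
    trace$t_s >= event_start_s - window_s & trace$t_s < event_start_s
  if (!any(use)) return(NA_real_)
  mean(trace$z_ohm[use])
}

#' Impedance of one volume step
#'
#' For a static-volume window, selects the channel's usable 10 s multiplexing
#' slot whose midpoint is closest to the window midpoint (ties broken toward
#' the earlier slot -- deterministic and causal) and returns its mean
#' impedance. Slots overlapping an avoid span (e.g. a compliance-balloon
#' inflation, padded by `guard_s`) are never used, so the measurement window
#' never coincides with the compliance check.
#'
#' @param trace Tibble with `t_s`, `z_ohm`, `quality` for one channel.
#' @param window Numeric `c(start, end)` of the static-volume period.
#' @param avoid Optional tibble with `start_s`, `end_s` spans to exclude.
#' @param guard_s Padding around avoid spans, seconds (default 5).
#' @param slot_s Slot length, seconds (default 10).
#' @return Mean impedance of the chosen slot (ohms), or `NA` if no usable
#'   slot exists in the window.
#' @export
step_impedance <- function(trace, window, avoid = NULL, guard_s = 5,
                           slot_s = 10) {
  use <- trace$quality & is.finite(trace$z_ohm) &
    trace$t_s >= window[1] & trace$t_s < window[2]
  if (!any(use)) return(NA_real_)
  slot <- floor(trace$t_s[use] / slot_s)
  slots <- sort(unique(slot))
  mid <- (slots + 0.5) * slot_s
  keep <- mid - slot_s / 2 >= window[1] & mid + slot_s / 2 <= window[2]
  if (!is.null(avoid) && nrow(avoid) > 0) {
    for (i in seq_len(nrow(avoid))) {
      keep <- keep & (mid + slot_s / 2 <= avoid$start_s[i] - guard_s |
                        mid - slot_s / 2 >= avoid$end_s[i] + guard_s)
    }
  }
  if (!any(keep)) return(NA_real_)
  slots <- slots[keep]
  mid <- mid[keep]
  target <- mean(window)
  dist <- abs(mid - target)
  best <- slots[order(dist, mid)][1]     # tie -> earlier slot
  mean(trace$z_ohm[use][slot == best])
}

#' Impedance change over an event
#'
#' `dZ = Z_final - Z_0`: the difference between the impedance at the event's
#' final volume and the zero-volume reference. Undefined (NA) when either
#' side is undefined.
#'
#' @param z_final,z_v0 Impedances in ohms (vectorised).
#' @return Impedance change, ohms.
#' @export
delta_z <- function(z_final, z_v0) z_final - z_v0

#' Discriminatory index
#'
#' `DI = dZ / dICP`, the ratio of impedance change to pressure change over an
#' event. Both injury mechanisms raise ICP, but the insulative (ischemia-like)
#' mass effect raises impedance while conductive hemorrhage lowers it, so the
#' sign of DI identifies the underlying etiology: positive for high-impedance
#' injury, negative for low-impedance injury.
#'
#' @param delta_z Impedance change, ohms (vectorised).
#' @param delta_icp Pressure change, mmHg.
#' @param eps Minimum credible |dICP|, mmHg (default 0.1); below it there is
#'   no pressure response and DI is undefined (NA).
#' @return DI in ohms/mmHg.
#' @export
#' @examples
#' discriminatory_index(10, 5)   # 2
#' discriminatory_index(-6, 3)   # -2
discriminatory_index <- function(delta_z, delta_icp, eps = 0.1) {
  ifelse(abs(delta_icp) > eps, delta_z / delta_icp, NA_real_)
}

#' Pearson correlation between impedance and ICP
#'
#' Standard product-moment correlation of paired samples. Pair the two
#' streams with [align_icp_slots()] first: ICP is averaged within each of the
#' channel's 10 s slots because the streams have different native rates.
#'
#' @param z,icp Equal-length paired numeric vectors.
#' @return r in `[-1, 1]`, or `NA` if fewer than 3 complete pairs or either
#'   series has zero variance.
#' @export
pearson_z_icp <- function(z, icp) {
  ok <- is.finite(z) & is.finite(icp)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(z[ok]) == 0 || stats::sd(icp[ok]) == 0) return(NA_real_)
  stats::cor(z[ok], icp[ok])
}

#' Slot-aligned impedance and ICP series
#'
#' Averages a channel's usable impedance samples and the ICP samples within
#' each of the channel's active 10 s slots over a time span, producing the
#' paired series used for impedance-ICP correlation.
#'
#' @param trace Tibble with `t_s`, `z_ohm`, `quality` for one channel.
#' @param icp Tibble with `t_s`, `icp_mmhg`.
#' @param span Numeric `c(start, end)` seconds.
#' @param slot_s Slot length (default 10).
#' @return Tibble with `t_s` (slot midpoint), `z_ohm`, `icp_mmhg`.
#' @export
align_icp_slots <- function(trace, icp, span, slot_s = 10) {
  use <- trace$quality & is.finite(trace$z_ohm) &
    trace$t_s >= span[1] & trace$t_s < span[2]
  if (!any(use)) {
    return(tibble::tibble(t_s = numeric(), z_ohm = numeric(),
                          icp_mmhg = numeric()))
  }
  slot <- floor(trace$t_s[use] / slot_s)
  z_m <- tapply(trace$z_ohm[use], slot, mean)
  slots <- as.numeric(names(z_m))
  icp_slot <- floor(icp$t_s / slot_s)
  icp_m <- tapply(icp$icp_mmhg, icp_slot, mean)
  icp_v <- icp_m[as.character(slots)]
  tibble::tibble(t_s = (slots + 0.5) * slot_s, z_ohm = as.numeric(z_m),
                 icp_mmhg = as.numeric(icp_v))
}

avoid_spans <- function(rec, labels = c("icc", "ct"), default_duration_s = 30) {
  ev <- rec$events[rec$events$label %in% labels, ]
  dur <- ifelse(is.na(ev$duration_s), default_duration_s, ev$duration_s)
  tibble::tibble(start_s = ev$t_s, end_s = ev$t_s + dur)
}

# compress a recording to per-slot means: one row per (channel, 10 s slot)
# with the usable-sample mean, count and slot midpoint, plus ICP slot means.
# All event metrics are slot-level quantities, so this single pass replaces
# repeated per-window averaging.
slot_table <- function(rec, slot_s = 10) {
  ch <- rec$channels
  use <- ch$quality & is.finite(ch$z_ohm)
  slot <- floor(ch$t_s[use] / slot_s)
  chan <- ch$channel[use]
  key <- slot * 10 + chan            # channel ids 1..8 < 10
  z_sum <- rowsum(ch$z_ohm[use], key)
  n <- rowsum(rep(1, sum(use)), key)
  keys <- as.numeric(rownames(z_sum))
  slots <- tibble::tibble(channel = as.integer(keys %% 10),
                          slot = floor(keys / 10),
                          z_ohm = as.numeric(z_sum / n),
                          n_usable = as.integer(n))
  slots$t_mid <- (slots$slot + 0.5) * slot_s
  islot <- floor(rec$icp$t_s / slot_s)
  icp_sum <- rowsum(rec$icp$icp_mmhg, islot)
  icp_n <- rowsum(rep(1, nrow(rec$icp)), islot)
  icp <- tibble::tibble(slot = as.numeric(rownames(icp_sum)),
                        icp_mmhg = as.numeric(icp_sum / icp_n))
  list(slots = slots, icp = icp, slot_s = slot_s)
}

# slot-level step_impedance on plain per-channel vectors: nearest usable
# whole slot to the window centre, avoiding padded spans; ties toward the
# earlier slot. ch = list(t_mid, z, n, slot) for one channel.
slot_step_impedance <- function(ch, window, avoid_lo = NULL, avoid_hi = NULL,
                                slot_s = 10) {
  lo <- ch$t_mid - slot_s / 2
  hi <- ch$t_mid + slot_s / 2
  keep <- lo >= window[1] & hi <= window[2]
  if (length(avoid_lo) > 0 && any(keep)) {
    for (i in seq_along(avoid_lo)) {
      keep <- keep & (hi <= avoid_lo[i] | lo >= avoid_hi[i])
    }
  }
  if (!any(keep)) return(NA_real_)
  target <- (window[1] + window[2]) / 2
  t_c <- ch$t_mid[keep]
  z_c <- ch$z[keep]
  z_c[order(abs(t_c - target), t_c)][1]
}

#' Event metrics for every phase of a recording
#'
#' The core quantitative chain. For each analysis phase and channel:
#' the zero-volume reference impedance (80 s pre-event), per-step impedances
#' (10 s slot nearest each static window's midpoint, avoiding compliance
#' checks), the event impedance change `dZ`, the event pressure change
#' `dICP`, the discriminatory index `DI = dZ/dICP`, and the impedance-ICP
#' Pearson correlation over the phase. Global (non-stepped) phases use their
#' final 5 min window as the "final volume" window.
#'
#' @param rec A `bim_recording` (preprocess and de-trend first as desired).
#' @param protocol The `bim_protocol`.
#' @param phases Phases to analyse (default: all non-baseline phases).
#' @param quality Optional `bim_quality` report; excluded channel-phase
#'   traces yield NA metrics.
#' @param guard_s Guard around compliance/CT spans when picking step slots.
#' @param di_eps Minimum |dICP| for a defined DI, mmHg.
#' @return List of class `bim_metrics`: `channels` (one row per
#'   phase-channel) and `steps` (one row per phase-channel-step).
#' @export
compute_event_metrics <- function(rec, protocol,
                                  phases = setdiff(protocol$phase, "baseline"),
                                  quality = NULL, guard_s = 5, di_eps = 0.1) {
  ph <- protocol_phases(protocol)
  steps_all <- protocol_steps(protocol)
  avoid <- avoid_spans(rec)
  avoid_lo <- avoid$start_s - guard_s
  avoid_hi <- avoid$end_s + guard_s
  st_tab <- slot_table(rec)
  slots <- st_tab$slots
  icp_by_slot <- st_tab$icp
  # plain per-channel vectors for the hot loop
  by_ch <- lapply(1:8, function(c_id) {
    k <- slots$channel == c_id
    list(t_mid = slots$t_mid[k], z = slots$z_ohm[k], n = slots$n_usable[k],
         slot = slots$slot[k])
  })
  chan_rows <- list(); step_rows <- list()
  for (phase in phases) {
    i <- match(phase, ph$phase)
    start <- ph$start_s[i]; end <- ph$end_s[i]
    st <- steps_all[steps_all$phase == phase, ]
    proto_row <- protocol[protocol$phase == phase, ]
    excluded <- rep(FALSE, 8)
    if (!is.null(quality)) {
      q <- quality[quality$phase == phase, ]
      excluded <- q$excluded[match(1:8, q$channel)]
    }
    # event pressure change: final window mean minus 80 s pre-event mean
    final_win <- if (nrow(st) > 0) {
      c(st$t_s[nrow(st)], st$t_s[nrow(st)] + proto_row$step_interval_s)
    } else c(end - 300, end)
    icp_pre <- mean(rec$icp$icp_mmhg[rec$icp$t_s >= start - 80 &
                                       rec$icp$t_s < start])
    icp_fin <- mean(rec$icp$icp_mmhg[rec$icp$t_s >= final_win[1] &
                                       rec$icp$t_s < final_win[2]])
    d_icp <- icp_fin - icp_pre
    for (c_id in 1:8) {
      if (excluded[c_id]) {
        chan_rows[[length(chan_rows) + 1]] <- list(
          phase = phase, channel = c_id, z_v0 = NA_real_, z_final = NA_real_,
          delta_z = NA_real_, delta_icp = d_icp, di = NA_real_,
          pearson_r = NA_real_)
        next
      }
      s_ch <- by_ch[[c_id]]
      in_v0 <- s_ch$t_mid - 5 >= start - 80 & s_ch$t_mid + 5 <= start
      z0 <- if (any(in_v0)) {
        sum(s_ch$z[in_v0] * s_ch$n[in_v0]) / sum(s_ch$n[in_v0])
      } else NA_real_
      if (nrow(st) > 0) {
        z_vn <- vapply(seq_len(nrow(st)), function(k) {
          win <- c(st$t_s[k], st$t_s[k] + proto_row$step_interval_s)
          slot_step_impedance(s_ch, win, avoid_lo, avoid_hi)
        }, numeric(1))
        step_rows[[length(step_rows) + 1]] <- list(
          phase = rep(phase, nrow(st)), channel = rep(c_id, nrow(st)),
          step = st$step, volume_ml = abs(st$volume_ml),
          t_s = st$t_s + proto_row$step_interval_s / 2, z_vn = z_vn,
          z_v0 = rep(z0, nrow(st)))
        z_fin <- z_vn[length(z_vn)]
      } else {
        z_fin <- slot_step_impedance(s_ch, final_win, avoid_lo, avoid_hi)
      }
      in_ph <- s_ch$t_mid >= start & s_ch$t_mid < end
      icp_pair <- icp_by_slot$icp_mmhg[match(s_ch$slot[in_ph],
                                             icp_by_slot$slot)]
      r <- pearson_z_icp(s_ch$z[in_ph], icp_pair)
      dz <- delta_z(z_fin, z0)
      chan_rows[[length(chan_rows) + 1]] <- list(
        phase = phase, channel = c_id, z_v0 = z0, z_final = z_fin,
        delta_z = dz, delta_icp = d_icp,
        di = discriminatory_index(dz, d_icp, eps = di_eps), pearson_r = r)
    }
  }
  bind_plain <- function(rows) {
    if (length(rows) == 0) return(tibble::tibble())
    cols <- lapply(names(rows[[1]]), function(nm) {
      unlist(lapply(rows, `[[`, nm), use.names = FALSE)
    })
    names(cols) <- names(rows[[1]])
    tibble::as_tibble(cols)
  }
  structure(list(channels = bind_plain(chan_rows),
                 steps = bind_plain(step_rows)),
            class = "bim_metrics")
}

#' Threshold detection of an intracranial volume change
#'
#' Scans the per-step impedance changes of a stepped phase and reports the
#' first volume step at which the detection signal crosses the threshold.
#' The signal is the across-usable-channel mean of `z_vn - z_v0`
#' (`"mean-channel"`, also used for `"non-detrended"` metrics computed
#' without baseline de-trending) or a designated nearest channel's change
#' (`"closest-channel"`). The default threshold, 7.1 ohms, is the
#' system-resolution threshold derived from the monitor's SNR with a 10x
#' safety factor; it is configuration, not recomputed.
#'
#' @param metrics A `bim_metrics` from [compute_event_metrics()].
#' @param phase Stepped phase to scan (default `"inflation"`).
#' @param threshold_ohm Detection threshold (default 7.1).
#' @param mode `"mean-channel"`, `"closest-channel"` or `"non-detrended"`.
#' @param closest_channel Channel id, required for `"closest-channel"`.
#' @return One-row tibble: `phase`, `mode`, `detected`,
#'   `detection_volume_ml`, `detection_time_s`, `signal_at_detection`.
#' @export
detect_volume_change <- function(metrics, phase = "inflation",
                                 threshold_ohm = 7.1,
                                 mode = c("mean-channel", "closest-channel",
                                          "non-detrended"),
                                 closest_channel = NULL) {
  mode <- match.arg(mode)
  st <- metrics$steps[metrics$steps$phase == phase, ]
  if (nrow(st) == 0) stop("no step data for phase ", phase, call. = FALSE)
  if (mode == "closest-channel") {
    if (is.null(closest_channel)) {
      stop("mode 'closest-channel' requires a designated channel",
           call. = FALSE)
    }
    st <- st[st$channel == closest_channel, ]
  }
  sig <- st |>
    dplyr::mutate(dz = .data$z_vn - .data$z_v0) |>
    dplyr::group_by(.data$step, .data$volume_ml, .data$t_s) |>
    dplyr::summarise(signal = mean(.data$dz, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(.data$step)
  hit <- which(abs(sig$signal) >= threshold_ohm)
  if (length(hit) == 0) {
    return(tibble::tibble(phase = phase, mode = mode, detected = FALSE,
                          detection_volume_ml = NA_real_,
                          detection_time_s = NA_real_,
                          signal_at_detection = NA_real_))
  }
  k <- hit[1]
  tibble::tibble(phase = phase, mode = mode, detected = TRUE,
                 detection_volume_ml = sig$volume_ml[k],
                 detection_time_s = sig$t_s[k],
                 signal_at_detection = sig$signal[k])
}

#' @export
print.bim_metrics <- function(x, ...) {
  cat("<bim_metrics> ", length(unique(x$channels$phase)), " phases x 8 channels, ",
      nrow(x$steps), " step measurements\n", sep = "")
  invisible(x)
}
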