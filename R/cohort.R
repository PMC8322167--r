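#' Simulate a cohort of subjects
#'
#' Generates `n_subjects` recordings from a scenario template with
#' per-subject variation: baseline ICP drawn uniformly in 8-15 mmHg and
#' per-channel baseline impedances in 1000 * (1 +/- 0.1) ohms, emulating the
#' wide range of baselines seen across animals. Per-subject seeds are derived
#' from the master seed by a fixed counter scheme, so cohorts are reproducible
#' and extensible.
#'
#' @param n_subjects Number of subjects (default 9).
#' @param scenario Scenario template, a `bim_scenario`.
#' @param seed Master integer seed.
#' @param fs Impedance sampling rate, Hz (default 50; reduce for large Monte
#'   Carlo sweeps -- the analysis consumes 10 s slot means, so the rate only
#'   rescales slot-mean noise).
#' @param p0_range Range of per-subject baseline ICP, mmHg.
#' @return List of class `bim_cohort` with `recordings`, `scenario`, `seed`.
#' @export
simulate_cohort <- function(n_subjects = 9, scenario = injury_scenario(),
                            seed = 1, fs = 50, p0_range = c(8, 15)) {
  stopifnot(n_subjects >= 1)
  recordings <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    seed_i <- (abs(seed) %% 20000) * 100003 + i * 101
    scn <- scenario
    scn$elastance$p0 <- withr::with_seed(seed_i, {
      stats::runif(1, p0_range[1], p0_range[2])
    })
    scn$seed <- seed_i + 1
    recordings[[i]] <- synthesize_recording(scn, fs = fs,
                                            subject_id = sprintf("subj-%02d", i))
  }
  structure(list(recordings = recordings, scenario = scenario, seed = seed),
            class = "bim_cohort")
}

#' @export
print.bim_cohort <- function(x, ...) {
  cat("<bim_cohort> ", length(x$recordings), " subjects, master seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Analyze a cohort end to end
#'
#' Runs the full pipeline on every subject -- preprocessing (CT masking, step
#' artifacts, quality exclusion), baseline de-trending, event metrics -- then
#' assembles cohort-level results: per-subject detection of the inflation
#' volume change, per-subject mean discriminatory index per event,
#' localization maps with the threshold classifier, and the focal/global
#' variance statistics.
#'
#' @param cohort A `bim_cohort` (or plain list of `bim_recording`s).
#' @param protocol Protocol; defaults to the cohort scenario's protocol.
#' @param detrend De-trend inflation against late baseline (default TRUE).
#' @param preprocess Run artifact filtering and exclusion (default TRUE).
#' @param threshold_ohm Detection threshold (default 7.1).
#' @param detection_mode Passed to [detect_volume_change()].
#' @param closest_channel Designated channel for `"closest-channel"` mode.
#' @param flat_range_ohm Localization degeneracy floor (default 7.1).
#' @return List of class `bim_cohort_analysis`: `metrics` (per
#'   subject-phase-channel tibble), `detections`, `di_subject`,
#'   `localization`, `variance`, `quality`.
#' @export
analyze_cohort <- function(cohort, protocol = NULL, detrend = TRUE,
                           preprocess = TRUE, threshold_ohm = 7.1,
                           detection_mode = "mean-channel",
                           closest_channel = NULL, flat_range_ohm = 7.1) {
  recs <- if (inherits(cohort, "bim_cohort")) cohort$recordings else cohort
  if (is.null(protocol)) {
    protocol <- if (inherits(cohort, "bim_cohort")) {
      cohort$scenario$protocol
    } else default_protocol()
  }
  all_metrics <- list(); detections <- list(); quality <- list()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    subject <- rec$meta$subject_id %||% paste0("subj-", i)
    q <- NULL
    if (preprocess) {
      prep <- preprocess_recording(rec, protocol)
      rec <- prep$recording
      q <- prep$quality
      quality[[i]] <- dplyr::mutate(prep$quality, subject = subject,
                                    .before = 1)
    }
    rec_d <- if (detrend) detrend_recording(rec, protocol)$recording else rec
    m <- compute_event_metrics(rec_d, protocol, quality = q)
    all_metrics[[i]] <- dplyr::mutate(m$channels, subject = subject,
                                      .before = 1)
    detections[[i]] <- dplyr::mutate(
      detect_volume_change(m, "inflation", threshold_ohm = threshold_ohm,
                           mode = if (detrend) detection_mode else "non-detrended",
                           closest_channel = closest_channel),
      subject = subject, .before = 1)
  }
  metrics <- dplyr::bind_rows(all_metrics)
  di_subject <- metrics |>
    dplyr::group_by(.data$subject, .data$phase) |>
    dplyr::summarise(mean_di = mean(.data$di, na.rm = TRUE),
                     mean_delta_z = mean(.data$delta_z, na.rm = TRUE),
                     delta_icp = .data$delta_icp[1], .groups = "drop")
  structure(list(metrics = metrics,
                 detections = dplyr::bind_rows(detections),
                 di_subject = di_subject,
                 localization = localize_events(metrics,
                                                flat_range_ohm = flat_range_ohm),
                 variance = variance_summary(metrics),
                 quality = if (preprocess) dplyr::bind_rows(quality) else NULL,
                 threshold_ohm = threshold_ohm),
            class = "bim_cohort_analysis")
}

#' Simulate and analyze a cohort in one call
#'
#' @inheritParams simulate_cohort
#' @inheritParams analyze_cohort
#' @param out_dir Optional directory: each subject's recording bundle is
#'   written there with [write_recording()].
#' @param ... Passed to [analyze_cohort()].
#' @return A `bim_cohort_analysis` with a `manifest` attribute (seed,
#'   n_subjects, fs, timestamp, package version).
#' @export
run_cohort <- function(n_subjects = 9, scenario = injury_scenario(),
                       seed = 1, fs = 50, out_dir = NULL, ...) {
  cohort <- simulate_cohort(n_subjects = n_subjects, scenario = scenario,
                            seed = seed, fs = fs)
  if (!is.null(out_dir)) {
    for (rec in cohort$recordings) {
      write_recording(rec, file.path(out_dir, rec$meta$subject_id))
    }
  }
  res <- analyze_cohort(cohort, ...)
  attr(res, "manifest") <- list(
    seed = seed, n_subjects = n_subjects, fs = fs,
    timestamp = format(Sys.time(), tz = "UTC"),
    version = as.character(utils::packageVersion("bimon")))
  res
}

#' @export
print.bim_cohort_analysis <- function(x, ...) {
  g <- glance(x)
  cat("<bim_cohort_analysis> ", g$n_subjects, " subjects\n", sep = "")
  cat("  detection: ", g$n_detected, "/", g$n_subjects,
      " subjects, mean volume ",
      signif(g$mean_detection_volume_ml, 3), " mL at ", x$threshold_ohm,
      " ohm\n", sep = "")
  cat("  mean DI: inflation ", signif(g$mean_di_inflation, 3),
      ", hematoma ", signif(g$mean_di_hematoma, 3), " ohm/mmHg\n", sep = "")
  cat("  localization: inflation -> ", g$inflation_label,
      " (element ", g$inflation_element, "), hematoma -> ",
      g$hematoma_label, " (element ", g$hematoma_element, ")\n", sep = "")
  cat("  focal/global: Levene p = ", format.pval(g$levene_p),
      ", Welch p = ", format.pval(g$welch_p), ", var(focal) > var(global) in ",
      g$n_focal_greater, "/", g$n_subjects, " subjects\n", sep = "")
  invisible(x)
}

#' Demodulation-chain characterization on known loads
#'
#' End-to-end exercise of the carrier path: synthesizes noisy 50 kHz carrier
#' voltage/current blocks across known resistor loads at the drive current,
#' demodulates them with the matched filter to a 50 Hz impedance stream,
#' measures per-load SNR, fits the linear calibration on the calibration
#' loads and evaluates held-out prediction accuracy.
#'
#' Noise is placed on voltage and current so the demodulated impedance
#' series attains approximately `snr_target_db` at each load.
#'
#' @param loads_cal Calibration load resistances, ohms (default five spanning
#'   10 ohm - 2 kohm).
#' @param loads_holdout Held-out loads, ohms (default 470 and 1500).
#' @param snr_target_db Target impedance-series SNR, dB (default 84).
#' @param current_a_pp Drive current, amperes peak-to-peak (default 2.3 mA).
#' @param f_carrier,f_sample Carrier/sampling frequency, Hz.
#' @param block_s Demodulation block, seconds (default 0.02).
#' @param n_blocks Impedance samples per load (default 50).
#' @param seed Integer seed.
#' @return List of class `bim_demod_characterization`: `per_load` (tibble
#'   `r_ohm`, `role`, `z_mean`, `snr_db`), `fit` (`bim_calibration`),
#'   `accuracy_pct`.
#' @export
characterize_demodulation <- function(loads_cal = c(10, 50, 200, 1000, 2000),
                                      loads_holdout = c(470, 1500),
                                      snr_target_db = 84,
                                      current_a_pp = 2.3e-3,
                                      f_carrier = 50e3, f_sample = 250e3,
                                      block_s = 0.02, n_blocks = 50,
                                      seed = 1) {
  n_block <- round(block_s * f_sample)
  a_i <- current_a_pp / 2
  rel <- 10^(-snr_target_db / 20)
  loads <- c(loads_cal, loads_holdout)
  role <- rep(c("calibration", "holdout"),
              c(length(loads_cal), length(loads_holdout)))
  rows <- withr::with_seed(seed, {
    lapply(seq_along(loads), function(j) {
      r <- loads[j]
      a_v <- a_i * r
      # split the target impedance-series variance equally between the two
      # amplitude estimates; matched-filter amplitude sd = noise_sd*sqrt(2/N)
      sd_v <- rel / sqrt(2) * a_v / sqrt(2 / n_block)
      sd_i <- rel / sqrt(2) * a_i / sqrt(2 / n_block)
      n <- n_blocks * n_block
      v <- synthesize_carrier_block(a_v, f_carrier, f_sample, n,
                                    noise_sd = sd_v, phase = stats::runif(1, 0, 2 * pi))
      cur <- synthesize_carrier_block(a_i, f_carrier, f_sample, n,
                                      noise_sd = sd_i, phase = stats::runif(1, 0, 2 * pi))
      raw <- raw_acquisition(v, cur, f_carrier, f_sample)
      z <- compute_impedance_series(raw, block_s = block_s)
      tibble::tibble(r_ohm = r, role = role[j],
                     z_mean = mean(z$z_ohm[z$quality]),
                     snr_db = snr_db(z$z_ohm[z$quality]))
    })
  })
  per_load <- dplyr::bind_rows(rows)
  cal <- per_load[per_load$role == "calibration", ]
  hold <- per_load[per_load$role == "holdout", ]
  fit <- calibrate_linear(cal$z_mean, cal$r_ohm)
  acc <- calibration_accuracy(fit, hold$z_mean, hold$r_ohm)
  structure(list(per_load = per_load, fit = fit, accuracy_pct = acc),
            class = "bim_demod_characterization")
}

#' @export
print.bim_demod_characterization <- function(x, ...) {
  cat("<bim_demod_characterization> held-out accuracy ",
      signif(x$accuracy_pct, 5), "%, mean SNR ",
      signif(mean(x$per_load$snr_db), 4), " dB\n", sep = "")
  invisible(x)
}
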