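test_that("CT masking covers exactly the padded burst span, mask-only", {
  scn <- clean_scenario(seed = 6)
  rec <- synthesize_recording(scn, fs = 1)
  # no CT events -> no-op
  expect_identical(flag_ct_windows(rec)$channels, rec$channels)
  rec$events <- dplyr::bind_rows(
    rec$events, tibble::tibble(label = "ct", t_s = 100, duration_s = 30))
  out <- flag_ct_windows(rec, pad_s = 5)
  masked_t <- out$channels$t_s[!out$channels$quality]
  expect_true(all(masked_t >= 95 & masked_t <= 135))
  expect_true(all(!out$channels$quality[out$channels$t_s >= 95 &
                                          out$channels$t_s <= 135]))
  # values untouched
  expect_identical(out$channels$z_ohm, rec$channels$z_ohm)
})

test_that("masking CT bursts restores the scenario noise level", {
  proto <- tiny_protocol()
  scn <- injury_scenario(
    protocol = proto, baseline_z = rep(1000, 8),
    drift = list(linear_ohm_per_hr = 0, settle_amplitude_ohm = 0,
                 settle_tau_s = 300),
    artifacts = artifact_spec(ct_bursts = tibble::tibble(
      t_s = seq(100, 1000, by = 90), duration_s = 30, extra_noise_sd = 10)),
    seed = 13)
  rec <- flag_ct_windows(synthesize_recording(scn, fs = 5))
  bl <- rec$channels[rec$channels$t_s < 1200 & rec$channels$quality, ]
  resid <- bl$z_ohm - 1000
  expect_equal(sd(resid), scn$noise_sd, tolerance = 0.1)
})

test_that("step detector flags asynchronous steps and spares protocol steps", {
  t <- seq(0, 1799, by = 2)
  # constant trace: nothing to flag
  res <- detect_step_artifacts(flat_trace(t, rep(1000, length(t))))
  expect_equal(nrow(res$detections), 0)
  # 50 ohm DC shift mid-baseline at t = 900
  z <- 1000 + 50 * (t >= 900)
  res <- detect_step_artifacts(flat_trace(t, z), step_threshold_ohm = 20)
  expect_equal(nrow(res$detections), 1)
  expect_lt(abs(res$detections$t_s - 900), 60 + 1)
  expect_equal(res$detections$magnitude_ohm, 50, tolerance = 1)
  # persistent shift: masked to the end of the trace
  expect_false(any(res$trace$quality[res$trace$t_s >= res$detections$t_s]))
  # identical change coincident with a declared volume step: signal, not
  # artifact
  res2 <- detect_step_artifacts(flat_trace(t, z), step_threshold_ohm = 20,
                                step_times = 900)
  expect_equal(nrow(res2$detections), 0)
  expect_true(all(res2$trace$quality))
})

test_that("masking after a step ends when the trace recovers", {
  t <- seq(0, 1799, by = 2)
  z <- 1000 + 80 * (t >= 600 & t < 1200)   # transient offset
  res <- detect_step_artifacts(flat_trace(t, z), step_threshold_ohm = 20)
  expect_gte(nrow(res$detections), 1)
  expect_false(any(res$trace$quality[t >= 660 & t < 1200]))
  expect_true(all(res$trace$quality[t >= 1260]))
})

test_that("quality exclusion drops corrupted traces and reports reasons", {
  proto <- tiny_protocol()
  # clean recording: nothing excluded
  rec <- synthesize_recording(injury_scenario(protocol = proto, seed = 2),
                              fs = 1)
  pp <- preprocess_recording(rec, proto)
  expect_equal(sum(pp$quality$excluded), 0)

  # droplet saturating most of the baseline of channel 2, recovering later:
  # exactly that one trace is excluded, with a reason (drift-free world so
  # recovery is governed by the droplet decay alone)
  scn <- clean_scenario(
    protocol = proto, seed = 3,
    artifacts = artifact_spec(droplets = tibble::tibble(
      channel = 2L, t_s = 150, offset_ohm = 300, tau_s = 300)))
  pp2 <- preprocess_recording(synthesize_recording(scn, fs = 1), proto)
  out <- pp2$quality[pp2$quality$excluded, ]
  expect_equal(nrow(out), 1)
  expect_equal(out$phase, "baseline")
  expect_equal(out$channel, 2L)
  expect_match(out$reason, "masked fraction")

  # degenerate thresholds exclude everything -> pipeline error
  expect_error(apply_quality_exclusion(rec, proto, max_masked_fraction = -1),
               "phase unusable")
})

test_that("exclusion counts grow with corruption severity", {
  proto <- tiny_protocol()
  n_excl <- vapply(c(0, 2, 6), function(k) {
    art <- if (k == 0) artifact_spec() else {
      artifact_spec(dc_shifts = tibble::tibble(
        channel = seq_len(k), t_s = 150, offset_ohm = 80))
    }
    scn <- injury_scenario(protocol = proto, seed = 4, artifacts = art)
    pp <- preprocess_recording(synthesize_recording(scn, fs = 1), proto)
    sum(pp$quality$excluded)
  }, numeric(1))
  expect_true(all(diff(n_excl) > 0))
})

test_that("de-trending cancels linear drift and is idempotent", {
  t <- seq(0, 4800, by = 2)
  # zero-slope baseline: unchanged up to intercept removal
  res <- detrend_baseline(flat_trace(t, rep(1000, length(t))),
                          baseline_window = c(600, 1200),
                          apply_span = range(t))
  expect_equal(res$trace$z_ohm, rep(0, length(t)), tolerance = 1e-9)
  expect_equal(res$slope, 0, tolerance = 1e-12)
  # pure linear drift at 36 ohm/h: residual is zero over the whole span
  z <- 1000 + 36 * t / 3600
  res2 <- detrend_baseline(flat_trace(t, z), baseline_window = c(600, 1200),
                           apply_span = range(t))
  expect_equal(max(abs(res2$trace$z_ohm)), 0, tolerance = 1e-9)
  expect_equal(res2$slope * 3600, 36, tolerance = 1e-9)
  # idempotence once the residual slope is ~0
  res3 <- detrend_baseline(res2$trace, baseline_window = c(600, 1200),
                           apply_span = range(t))
  expect_equal(res3$trace$z_ohm, res2$trace$z_ohm, tolerance = 1e-9)
  # unusable baseline -> the documented fallback error
  short <- flat_trace(t, z, quality = t > 2000)
  expect_error(detrend_baseline(short, baseline_window = c(600, 1200)),
               "without de-trending")
})

test_that("de-trended nearest-channel change matches the simulated gain", {
  proto <- tiny_protocol()
  scn <- injury_scenario(protocol = proto, seed = 5)   # drift + mild noise
  rec <- synthesize_recording(scn, fs = 1)
  det <- detrend_recording(rec, proto)
  m <- compute_event_metrics(det$recording, proto, phases = "inflation")
  dz3 <- m$channels$delta_z[m$channels$channel == scn$inclusion_sector]
  expect_equal(dz3, scn$focal_gain * 1.2, tolerance = 0.05 * 36)
})
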