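test_that("zero-volume impedance averages the pre-event reference window", {
  t <- seq(0, 1199, by = 2)
  tr <- flat_trace(t, rep(1000, length(t)))
  expect_equal(zero_volume_impedance(tr, 1200), 1000)
  # masked samples inside the span are excluded, not interpolated
  tr2 <- tr
  tr2$z_ohm[t >= 1140] <- 5000
  tr2$quality[t >= 1140] <- FALSE
  expect_equal(zero_volume_impedance(tr2, 1200), 1000)
  # no usable samples -> channel unusable for the event
  tr3 <- tr
  tr3$quality[t >= 1120] <- FALSE
  expect_true(is.na(zero_volume_impedance(tr3, 1200)))
  # standard-error bound on a simulated noisy baseline
  scn <- injury_scenario(protocol = tiny_protocol(), noise_sd = 0.7,
                         baseline_z = rep(1000, 8),
                         drift = list(linear_ohm_per_hr = 0,
                                      settle_amplitude_ohm = 0,
                                      settle_tau_s = 300),
                         seed = 17)
  rec <- synthesize_recording(scn, fs = 5)
  for (c_id in c(1, 4, 8)) {
    tr_c <- rec$channels[rec$channels$channel == c_id, ]
    z0 <- zero_volume_impedance(tr_c, 1200)
    n <- sum(tr_c$t_s >= 1120 & tr_c$t_s < 1200)
    expect_lt(abs(z0 - 1000), 3 * 0.7 / sqrt(n))
  }
})

test_that("step impedance picks the usable slot nearest the window middle", {
  # slots at [0,10), [80,90), [160,170), ... (channel 1 of the multiplex)
  t <- as.vector(outer(0:9, seq(0, 560, by = 80), `+`))
  z <- rep(seq(10, 80, by = 10), each = 10)    # slot index as value
  tr <- flat_trace(sort(t), z[order(t)])
  # window [140, 440] -> middle 290; slot mids 165/245/325/405 -> the slot
  # starting at 320 (35 s away) wins
  expect_equal(step_impedance(tr, c(140, 440)), 50)
  # exact tie: window [40, 210] -> middle 125, slot mids 85 and 165 both
  # 40 s away -> earlier slot wins
  expect_equal(step_impedance(tr, c(40, 210)), 20)
  # avoid span knocks out the winning slot; next nearest (mid 245) is chosen
  expect_equal(step_impedance(tr, c(140, 440),
                              avoid = tibble::tibble(start_s = 315,
                                                     end_s = 335)), 40)
  # no usable slot -> NA
  tr$quality <- FALSE
  expect_true(is.na(step_impedance(tr, c(140, 440))))
})

test_that("event impedance changes mirror between inflation and deflation", {
  scn <- clean_scenario(seed = 1)
  rec <- synthesize_recording(scn, fs = 1)
  m <- compute_event_metrics(rec, scn$protocol)
  ch <- m$channels
  infl <- ch[ch$phase == "inflation", ]
  defl <- ch[ch$phase == "deflation", ]
  expect_equal(defl$delta_z, -infl$delta_z, tolerance = 1e-9)
  # nearest channel carries gain * total volume exactly
  expect_equal(infl$delta_z[infl$channel == 3], 30 * 1.2, tolerance = 1e-9)
})

test_that("the 10 s window rule is robust against full-window averaging", {
  scn <- injury_scenario(protocol = tiny_protocol(), seed = 19,
                         baseline_z = rep(1000, 8))
  rec <- synthesize_recording(scn, fs = 2)
  det <- detrend_recording(rec, scn$protocol)$recording
  m <- compute_event_metrics(det, scn$protocol, phases = "inflation")
  steps <- m$steps
  ph <- protocol_phases(scn$protocol)
  start <- ph$start_s[ph$phase == "inflation"]
  for (c_id in c(2, 3, 7)) {
    tr <- det$channels[det$channels$channel == c_id, ]
    for (k in c(1, 4)) {
      win <- c(start + (k - 1) * 300, start + k * 300)
      full <- mean(tr$z_ohm[tr$quality & tr$t_s >= win[1] & tr$t_s < win[2]])
      ten_s <- steps$z_vn[steps$channel == c_id & steps$step == k]
      expect_lt(abs(ten_s - full), 1)
    }
  }
})

test_that("discriminatory index divides impedance change by pressure change", {
  expect_equal(discriminatory_index(10, 5), 2)
  expect_equal(discriminatory_index(-6, 3), -2)
  # undefined without a pressure response
  expect_true(is.na(discriminatory_index(10, 0.05)))
  # antisymmetry: negating the impedance change negates DI exactly
  dz <- c(-20, -3, 0.5, 12, 36)
  expect_equal(discriminatory_index(-dz, 4), -discriminatory_index(dz, 4))
})

test_that("impedance-ICP correlation behaves as a Pearson coefficient", {
  icp <- c(10, 12, 15, 18, 22, 30)
  expect_equal(pearson_z_icp(2 * icp + 1, icp), 1)
  expect_equal(pearson_z_icp(-icp, icp), -1)
  expect_true(is.na(pearson_z_icp(rep(5, 6), icp)))
  expect_true(is.na(pearson_z_icp(icp[1:2], icp[1:2])))
  # independent noise: |r| < 0.3 nearly always at n = 100
  hits <- vapply(1:100, function(s) {
    withr::with_seed(s, abs(cor(rnorm(100), rnorm(100))) < 0.3)
  }, logical(1))
  expect_gte(sum(hits), 99)
})

test_that("threshold detection crosses at the first analytic step", {
  scn <- clean_scenario(protocol = default_protocol(), focal_gain = 20,
                        seed = 2)
  rec <- synthesize_recording(scn, fs = 1)
  m <- compute_event_metrics(rec, scn$protocol)
  det <- detect_volume_change(m, threshold_ohm = 7.1,
                              mode = "closest-channel", closest_channel = 3)
  # 20 ohm/mL: first step with 20 * V >= 7.1 is V = 0.4 mL
  expect_true(det$detected)
  expect_equal(det$detection_volume_ml, 0.4)
  # threshold zero detects at the first step
  det0 <- detect_volume_change(m, threshold_ohm = 0,
                               mode = "closest-channel", closest_channel = 3)
  expect_equal(det0$detection_volume_ml, 0.1)
  # detection volume is nonincreasing as the threshold decreases
  vols <- vapply(c(20, 15, 10, 7.1, 3, 1), function(th) {
    detect_volume_change(m, threshold_ohm = th, mode = "closest-channel",
                         closest_channel = 3)$detection_volume_ml
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
  # closest-channel mode demands a designated channel
  expect_error(detect_volume_change(m, mode = "closest-channel"),
               "designated channel")
})

test_that("insulative events correlate with ICP more than conductive ones", {
  scn <- injury_scenario(protocol = tiny_protocol(), seed = 23)
  rec <- synthesize_recording(scn, fs = 1)
  det <- detrend_recording(rec, scn$protocol)$recording
  m <- compute_event_metrics(det, scn$protocol)
  ch <- m$channels
  r_infl <- mean(ch$pearson_r[ch$phase == "inflation"], na.rm = TRUE)
  r_hem <- mean(ch$pearson_r[ch$phase == "hematoma"], na.rm = TRUE)
  expect_gt(r_infl, r_hem)
  expect_gt(r_infl, 0)
})
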