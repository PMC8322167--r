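test_that("sector weights follow the wrapped Gaussian kernel", {
  expect_equal(sector_weight(90, 90, 45), 1)
  expect_equal(sector_weight(45, 90, 45), sector_weight(135, 90, 45))
  expect_equal(sector_weight(90, 45, 45), exp(-0.5))
  # wrapping: 350 vs 10 degrees is 20 degrees apart, not 340
  expect_equal(sector_weight(350, 10, 45), exp(-20^2 / (2 * 45^2)))
  expect_error(sector_weight(0, 0, 0))
})

test_that("ICP follows the exponential elastance curve of added volume", {
  p <- default_protocol()
  ph <- protocol_phases(p)
  el <- list(p0 = 10, e = 0.5)
  # flat at p0 with no volume (baseline span)
  t_bl <- seq(0, 1700, by = 10)
  expect_equal(simulate_icp(p, el, t_bl), rep(10, length(t_bl)))
  # 10 * exp(0.5 * 1.2) at full inflation
  t_full <- ph$end_s[ph$phase == "inflation"] - 1
  expect_equal(simulate_icp(p, el, t_full), 10 * exp(0.6), tolerance = 1e-10)
  # 12 discrete plateaus during inflation, monotone in volume
  t_infl <- seq(ph$start_s[2], ph$end_s[2] - 1, by = 5)
  icp <- simulate_icp(p, el, t_infl)
  expect_equal(length(unique(icp)), 12)
  expect_true(all(diff(icp) >= 0))
  # terminal phase decays toward zero
  t_term <- ph$end_s[6] - 1
  expect_lt(simulate_icp(p, el, t_term), 0.5)
})

test_that("injury deltas are sector-localized with the stated sign", {
  scn <- clean_scenario(protocol = default_protocol())
  ph <- protocol_phases(default_protocol())
  # zero volume -> zero response everywhere
  d0 <- simulate_injury_deltas(scn, c(0, 900))
  expect_true(all(d0 == 0))
  # insulative balloon: argmax at the inclusion sector, value gain * V
  t_full <- ph$end_s[ph$phase == "inflation"] - 1
  d <- simulate_injury_deltas(scn, t_full)
  expect_equal(which.max(d[1, ]), scn$inclusion_sector)
  expect_equal(d[1, scn$inclusion_sector], 30 * 1.2)
  # conductive blood at full injection (balloon back at zero, globals not
  # started): -30 * 1.2 = -36 ohm at the nearest channel
  t_hem <- ph$end_s[ph$phase == "hematoma"] - 1
  dh <- simulate_injury_deltas(scn, t_hem)
  expect_equal(dh[1, scn$inclusion_sector], -36, tolerance = 1e-9)
  expect_equal(which.min(dh[1, ]), scn$inclusion_sector)
  # deflation walks the inflation staircase back down to zero
  t_defl <- seq(ph$start_s[ph$phase == "deflation"],
                ph$end_s[ph$phase == "deflation"] - 1, by = 5)
  d_defl <- simulate_injury_deltas(scn, t_defl)[, scn$inclusion_sector]
  expect_true(all(diff(d_defl) <= 0))
  expect_equal(d_defl[length(d_defl)], 0)
  t_infl <- seq(ph$start_s[ph$phase == "inflation"],
                ph$end_s[ph$phase == "inflation"] - 1, by = 5)
  d_infl <- simulate_injury_deltas(scn, t_infl)[, scn$inclusion_sector]
  expect_equal(sort(unique(d_defl)),
               sort(c(0, setdiff(unique(d_infl), max(d_infl)))))
})

test_that("synthesis is deterministic and exact in the noise-free world", {
  scn <- clean_scenario(seed = 11)
  r1 <- synthesize_recording(scn, fs = 0.5)
  r2 <- synthesize_recording(scn, fs = 0.5)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$icp, r2$icp)
  # during baseline (V = 0, no drift/noise) every sample is its channel's
  # baseline impedance
  bl <- r1$channels[r1$channels$t_s < 1200, ]
  expect_equal(bl$z_ohm, rep(1000, nrow(bl)))
})

test_that("default noise level yields ~84 dB per-sample SNR at baseline", {
  scn <- injury_scenario(
    protocol = tiny_protocol(), baseline_z = rep(1000, 8),
    drift = list(linear_ohm_per_hr = 0, settle_amplitude_ohm = 0,
                 settle_tau_s = 300),
    seed = 21)
  rec <- synthesize_recording(scn, fs = 5)
  bl <- rec$channels[rec$channels$t_s < 1200, ]
  snrs <- vapply(1:8, function(c_id) {
    snr_db(bl$z_ohm[bl$channel == c_id])
  }, numeric(1))
  expect_true(all(abs(snrs - 84) < 1))
})

test_that("carrier synthesis refuses aliasing configurations", {
  expect_error(synthesize_carrier_block(1, 50e3, 50e3, 1000), "alias")
  # amplitude zero -> pure noise
  x <- synthesize_carrier_block(0, 50e3, 250e3, 1000, noise_sd = 0.1,
                                seed = 2)
  expect_equal(sd(x), 0.1, tolerance = 0.1)
  expect_equal(mean(x), 0, tolerance = 0.02)
  # determinism via seed
  expect_identical(synthesize_carrier_block(1, 50e3, 250e3, 500, 0.01, seed = 9),
                   synthesize_carrier_block(1, 50e3, 250e3, 500, 0.01, seed = 9))
})
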