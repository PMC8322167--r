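#' Angular sensitivity of a channel to a focal source
#'
#' Eight rotating surface-electrode pairs create eight angular sensitivity
#' sectors around the fixed intracranial electrodes. The forward model
#' weights a channel's response to a focal source by a Gaussian kernel in
#' wrapped angular distance: `w = exp(-d^2 / (2 * kernel_width^2))` with
#' `d <= 180` degrees.
#'
#' @param channel_angle,source_angle Angles in degrees (vectorised).
#' @param kernel_width Kernel width in degrees (> 0).
#' @return Weights in (0, 1].
#' @export
#' @examples
#' sector_weight(90, 90, 45)        # 1
#' sector_weight(90, 45, 45)        # exp(-0.5)
sector_weight <- function(channel_angle, source_angle, kernel_width) {
  stopifnot(kernel_width > 0)
  d <- abs(((channel_angle - source_angle + 180) %% 360) - 180)
  exp(-d^2 / (2 * kernel_width^2))
}

#' Channel and sector angles
#'
#' Channels (and sectors) are spaced 45 degrees apart; channel `c` sits at
#' `(c - 1) * 45` degrees.
#'
#' @param channel Integer channel/sector id(s) in 1-8.
#' @return Angle(s) in degrees.
#' @export
channel_angle <- function(channel = 1:8) (channel - 1) * 45

#' Simulate the ICP response to the injury protocol
#'
#' ICP follows a single-exponential craniospinal elastance curve,
#' `ICP(t) = p0 * exp(e * V(t))`, with `V(t)` the cumulative intracranial
#' volume added by the protocol (balloon + blood). The osmotic phase removes
#' an effective volume as a ramp over its first half; the terminal phase
#' decays ICP exponentially toward zero (loss of physiologic pressure).
#'
#' @param protocol A `bim_protocol`.
#' @param elastance List with `p0` (mmHg) and `e` (1/mL).
#' @param t Time grid, seconds.
#' @param osmotic_volume_ml Effective volume removed by the osmotic phase.
#' @param terminal_tau_s Terminal ICP decay constant, seconds.
#' @param noise_sd Additive Gaussian noise, mmHg (default 0; supply a seeded
#'   RNG context for reproducibility).
#' @return Numeric vector of ICP in mmHg, same length as `t`.
#' @export
simulate_icp <- function(protocol, elastance, t, osmotic_volume_ml = 1,
                         terminal_tau_s = 120, noise_sd = 0) {
  vol <- protocol_volume(protocol, t)
  ph <- protocol_phases(protocol)
  v_eff <- vol$v_total_ml - osmotic_volume_ml * phase_ramp(ph, "global_osmotic", t)
  icp <- elastance$p0 * exp(elastance$e * v_eff)
  i_term <- match("global_terminal", ph$phase)
  if (!is.na(i_term)) {
    t0 <- ph$start_s[i_term]
    after <- t >= t0
    if (any(after)) {
      v0 <- protocol_volume(protocol, t0)$v_total_ml -
        osmotic_volume_ml * phase_ramp(ph, "global_osmotic", t0)
      icp0 <- elastance$p0 * exp(elastance$e * v0)
      icp[after] <- icp0 * exp(-(t[after] - t0) / terminal_tau_s)
    }
  }
  if (noise_sd > 0) icp <- icp + stats::rnorm(length(t), 0, noise_sd)
  icp
}

# ramp 0 -> 1 over the first half of the named phase, 1 thereafter; 0 if the
# phase is absent
phase_ramp <- function(ph, phase, t) {
  i <- match(phase, ph$phase)
  if (is.na(i)) return(rep(0, length(t)))
  half <- (ph$end_s[i] - ph$start_s[i]) / 2
  pmin(pmax((t - ph$start_s[i]) / half, 0), 1)
}

#' Per-channel ground-truth impedance changes
#'
#' The simulator's forward model. Focal phases produce a sector-localised
#' response, `dZ_c(t) = sign * focal_gain * V(t) * w_c`, with `w_c` the
#' [sector_weight()] of channel `c` for the inclusion sector: positive for
#' the insulative balloon (inflation/deflation, which reverses as the balloon
#' volume falls) and negative for conductive blood. Global phases add a
#' uniform shift `global_gain * g(t)` on every channel, with `g` ramping over
#' the first half of the phase.
#'
#' @param scenario A `bim_scenario`.
#' @param t Time grid, seconds.
#' @return Matrix `length(t) x 8` of impedance changes in ohms (noise-free).
#' @export
simulate_injury_deltas <- function(scenario, t) {
  parts <- injury_delta_parts(scenario, t)
  w <- parts$weights
  out <- outer(parts$balloon, w) + outer(parts$blood_focal, w)
  out + parts$global_shift + parts$blood_diffuse
}

# shared forward-model components; synthesize_recording uses these per-sample
# to avoid materialising the full n x 8 matrix
injury_delta_parts <- function(scenario, t) {
  vol <- protocol_volume(scenario$protocol, t)
  ph <- protocol_phases(scenario$protocol)
  w <- sector_weight(channel_angle(1:8),
                     channel_angle(scenario$inclusion_sector),
                     scenario$kernel_width)
  s_balloon <- unname(scenario$focal_signs["inflation"])
  s_blood <- unname(scenario$focal_signs["hematoma"])
  track <- scenario$tracking_fraction
  g <- scenario$global_gain *
    (phase_ramp(ph, "global_osmotic", t) + phase_ramp(ph, "global_terminal", t))
  list(weights = w,
       balloon = s_balloon * scenario$focal_gain * vol$v_balloon_ml,
       blood_focal = s_blood * scenario$focal_gain * (1 - track) *
         vol$v_blood_ml,
       blood_diffuse = s_blood * scenario$focal_gain * track * mean(w) *
         vol$v_blood_ml,
       global_shift = g)
}

#' Synthesize a full multichannel recording
#'
#' Envelope-level synthesis of the monitor's output: per-channel 50 Hz
#' impedance samples inside each channel's active 10 s multiplexing slot
#' (channels cycle 1 to 8, 80 s period), with
#' `Z = baseline + drift + injury + artifacts + noise`. Drift is electrode
#' settling (saturating exponential rise) plus a linear trend. Sync events
#' record every phase start, volume step, compliance-balloon check (2 min
#' after each mass-effect step) and CT burst. Deterministic given the
#' scenario seed.
#'
#' @param scenario A `bim_scenario`.
#' @param fs Impedance sampling rate within the active slot, Hz (default 50).
#'   Down-stream analysis consumes 10 s slot means, so reduced rates trade
#'   slot-mean noise for speed.
#' @param subject_id Subject identifier stored in metadata.
#' @return A `bim_recording`.
#' @export
synthesize_recording <- function(scenario, fs = 50, subject_id = "sim-1") {
  proto <- scenario$protocol
  duration <- sum(proto$duration_s)
  withr::with_seed(scenario$seed, {
    baseline_z <- scenario$baseline_z %||% stats::runif(8, 900, 1100)
    n <- floor(duration * fs)
    t <- (seq_len(n) - 1) / fs
    ch <- slot_channel(t)
    parts <- injury_delta_parts(scenario, t)
    dz <- parts$balloon * parts$weights[ch] +
      parts$blood_focal * parts$weights[ch] +
      parts$blood_diffuse + parts$global_shift
    dr <- scenario$drift
    drift <- dr$linear_ohm_per_hr * t / 3600 +
      dr$settle_amplitude_ohm * (1 - exp(-t / dr$settle_tau_s))
    z <- baseline_z[ch] + drift + dz
    if (scenario$noise_sd > 0) z <- z + stats::rnorm(n, 0, scenario$noise_sd)
    art <- scenario$artifacts
    for (i in seq_len(nrow(art$ct_bursts))) {
      b <- art$ct_bursts[i, ]
      idx <- which(t >= b$t_s & t < b$t_s + b$duration_s)
      if (length(idx) > 0 && b$extra_noise_sd > 0) {
        z[idx] <- z[idx] + stats::rnorm(length(idx), 0, b$extra_noise_sd)
      }
    }
    for (i in seq_len(nrow(art$dc_shifts))) {
      s <- art$dc_shifts[i, ]
      idx <- which(ch == s$channel & t >= s$t_s)
      z[idx] <- z[idx] + s$offset_ohm
    }
    for (i in seq_len(nrow(art$droplets))) {
      d <- art$droplets[i, ]
      idx <- which(ch == d$channel & t >= d$t_s)
      z[idx] <- z[idx] + d$offset_ohm * exp(-(t[idx] - d$t_s) / d$tau_s)
    }
    t_icp <- seq(0, duration - 1, by = 1)
    icp <- simulate_icp(proto, scenario$elastance, t_icp,
                        osmotic_volume_ml = scenario$osmotic_volume_ml,
                        terminal_tau_s = scenario$terminal_tau_s,
                        noise_sd = scenario$icp_noise_sd)
    channels <- tibble::tibble(channel = ch, t_s = t, z_ohm = z,
                               quality = TRUE)
    channels <- channels[order(channels$channel, channels$t_s), ]
    bim_recording(
      channels = channels,
      icp = tibble::tibble(t_s = t_icp, icp_mmhg = icp),
      events = scenario_events(scenario),
      meta = list(subject_id = subject_id, seed = scenario$seed,
                  schema_version = 1L,
                  inclusion_sector = scenario$inclusion_sector,
                  focal_gain = scenario$focal_gain,
                  fs = fs)
    )
  })
}

scenario_events <- function(scenario) {
  proto <- scenario$protocol
  ph <- protocol_phases(proto)
  steps <- protocol_steps(proto)
  ev <- dplyr::bind_rows(
    tibble::tibble(label = paste0("phase:", ph$phase), t_s = ph$start_s,
                   duration_s = NA_real_),
    tibble::tibble(label = paste0("step:", steps$phase, ":", steps$step),
                   t_s = steps$t_s, duration_s = NA_real_),
    # compliance (ICC) balloon check 2 min after each mass-effect step
    tibble::tibble(label = "icc", t_s = steps$t_s + 120, duration_s = 30),
    tibble::tibble(label = "ct", t_s = scenario$artifacts$ct_bursts$t_s,
                   duration_s = scenario$artifacts$ct_bursts$duration_s)
  )
  span_end <- sum(proto$duration_s)
  ev <- ev[ev$t_s <= span_end, ]
  ev[order(ev$t_s), ]
}

#' Synthesize one carrier-level voltage block
#'
#' A noisy sinusoidal carrier, `x[k] = A * sin(2 pi f k / fs + phi) + e[k]`,
#' used to exercise the matched-filter demodulator. The carrier phase is
#' drawn from the seed unless given. Sampling below four samples per carrier
#' cycle is refused: demodulating a 50 kHz carrier sampled at 50 kHz would
#' alias it to DC.
#'
#' @param amplitude_v Carrier amplitude, volts.
#' @param f_carrier,f_sample Carrier and sampling frequency, Hz
#'   (`f_sample >= 4 * f_carrier`).
#' @param n Number of samples.
#' @param noise_sd White-noise standard deviation, volts.
#' @param seed Optional integer seed (phase and noise).
#' @param phase Optional fixed carrier phase, radians.
#' @return Numeric vector of `n` voltage samples.
#' @export
synthesize_carrier_block <- function(amplitude_v, f_carrier, f_sample, n,
                                     noise_sd = 0, seed = NULL, phase = NULL) {
  if (f_sample < 4 * f_carrier) {
    stop("f_sample must be >= 4 * f_carrier: sampling at ", f_sample,
         " Hz aliases a ", f_carrier, " Hz carrier", call. = FALSE)
  }
  gen <- function() {
    phi <- phase %||% stats::runif(1, 0, 2 * pi)
    k <- seq_len(n) - 1
    x <- amplitude_v * sin(2 * pi * f_carrier * k / f_sample + phi)
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    x
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
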