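#' Artifact specification for the simulator
#'
#' Three artifact classes contaminate real bedside recordings and are
#' reproduced by the simulator: broadband noise bursts during active CT
#' acquisition (all channels), abrupt DC shifts on single electrodes
#' (electrical), and decaying offsets from fluid droplets landing on an
#' electrode (physiological).
#'
#' @param ct_bursts Tibble with `t_s`, `duration_s`, `extra_noise_sd` (ohms).
#' @param dc_shifts Tibble with `channel`, `t_s`, `offset_ohm` (persistent).
#' @param droplets Tibble with `channel`, `t_s`, `offset_ohm`, `tau_s`
#'   (exponential decay constant).
#' @return A list of class `bim_artifacts`.
#' @export
artifact_spec <- function(ct_bursts = NULL, dc_shifts = NULL, droplets = NULL) {
  ct_bursts <- tibble::as_tibble(ct_bursts %||% tibble::tibble(
    t_s = numeric(), duration_s = numeric(), extra_noise_sd = numeric()))
  dc_shifts <- tibble::as_tibble(dc_shifts %||% tibble::tibble(
    channel = integer(), t_s = numeric(), offset_ohm = numeric()))
  droplets <- tibble::as_tibble(droplets %||% tibble::tibble(
    channel = integer(), t_s = numeric(), offset_ohm = numeric(),
    tau_s = numeric()))
  if (any(ct_bursts$duration_s <= 0)) {
    stop("CT burst durations must be positive", call. = FALSE)
  }
  if (any(droplets$tau_s <= 0)) {
    stop("droplet decay constants must be positive", call. = FALSE)
  }
  structure(list(ct_bursts = ct_bursts, dc_shifts = dc_shifts,
                 droplets = droplets),
            class = "bim_artifacts")
}

#' CT bursts on the protocol's imaging schedule
#'
#' The experimental protocol acquires a CT after every volume step; this
#' helper builds the matching burst table (one burst per step, starting
#' shortly after the step).
#'
#' @param protocol A `bim_protocol`.
#' @param delay_s Burst onset after the volume step (default 150 s, after the
#'   compliance-balloon check).
#' @param duration_s Burst length (default 30 s).
#' @param extra_noise_sd Added noise during the burst, ohms (default 5).
#' @return A tibble suitable for [artifact_spec()]'s `ct_bursts`.
#' @export
ct_burst_schedule <- function(protocol, delay_s = 150, duration_s = 30,
                              extra_noise_sd = 5) {
  steps <- protocol_steps(protocol)
  tibble::tibble(t_s = steps$t_s + delay_s, duration_s = duration_s,
                 extra_noise_sd = extra_noise_sd)
}

#' Ground-truth injury scenario for the simulator
#'
#' Bundles everything the synthetic-data generator needs: the protocol, the
#' focal injury's location and electrical sign, the angular sensitivity
#' kernel, craniospinal elastance, electrode drift, measurement noise,
#' artifacts and the RNG seed. Defaults state the simulated world: a 1000-ohm
#' baseline channel set at 84 dB per-sample SNR, a 30 ohm/mL focal response in
#' sector 3, balloon (insulative, impedance up) and blood (conductive,
#' impedance down) contrast signs, and a two-parameter exponential
#' pressure-volume relation.
#'
#' @param protocol A `bim_protocol` (default [default_protocol()]).
#' @param inclusion_sector Integer 1-8; sector containing the focal injury
#'   (default 3).
#' @param focal_gain Ohms per mL of focal volume at the nearest channel
#'   (default 30).
#' @param kernel_width Angular spread of sector sensitivity in degrees
#'   (default 45, one sector).
#' @param baseline_z Per-channel baseline impedance in ohms; either length 8
#'   or length 1 (replicated). `NULL` (default) draws 8 values uniformly in
#'   1000 * (1 +/- 0.1) from the seed.
#' @param elastance List with `p0` (baseline ICP, mmHg; default 10) and `e`
#'   (elastance coefficient, 1/mL; default 0.5).
#' @param drift List with `linear_ohm_per_hr` (default 10),
#'   `settle_amplitude_ohm` (default 20) and `settle_tau_s` (default 300):
#'   electrode settling as a saturating exponential rise plus linear trend.
#'   The default settling constant completes settling within the 30 min
#'   baseline, consistent with estimating residual drift by a linear fit to
#'   the final 10 min of baseline.
#' @param noise_sd Per-sample Gaussian noise, ohms. Default
#'   `noise_sd_for_snr(84, 1000)` (~0.0631), i.e. 84 dB sample SNR at 1000
#'   ohms.
#' @param artifacts An [artifact_spec()] (default: none).
#' @param global_gain Magnitude of the uniform across-channel impedance shift
#'   in global phases, ohms (default 15).
#' @param focal_signs Named numeric: contrast sign per focal phase. Default
#'   `c(inflation = 1, deflation = 1, hematoma = -1)`: the balloon is
#'   insulative (+), blood conductive (-).
#' @param tracking_fraction Fraction of injected blood volume diverted away
#'   from the focal sector as a diffuse (uniform) contribution, emulating
#'   posterior blood tracking (default 0).
#' @param osmotic_volume_ml Effective intracranial volume removed by the
#'   osmotic phase, mL (default 1).
#' @param terminal_tau_s ICP decay constant of the terminal phase, seconds
#'   (default 120).
#' @param icp_noise_sd Additive ICP noise, mmHg (default 0.2).
#' @param seed Integer RNG seed (default 1).
#' @return A list of class `bim_scenario`.
#' @export
injury_scenario <- function(protocol = default_protocol(),
                            inclusion_sector = 3,
                            focal_gain = 30,
                            kernel_width = 45,
                            baseline_z = NULL,
                            elastance = list(p0 = 10, e = 0.5),
                            drift = list(linear_ohm_per_hr = 10,
                                         settle_amplitude_ohm = 20,
                                         settle_tau_s = 300),
                            noise_sd = noise_sd_for_snr(84, 1000),
                            artifacts = artifact_spec(),
                            global_gain = 15,
                            focal_signs = c(inflation = 1, deflation = 1,
                                            hematoma = -1),
                            tracking_fraction = 0,
                            osmotic_volume_ml = 1,
                            terminal_tau_s = 120,
                            icp_noise_sd = 0.2,
                            seed = 1L) {
  stopifnot(focal_gain > 0, kernel_width > 0, noise_sd >= 0,
            elastance$p0 > 0, elastance$e > 0,
            inclusion_sector %in% 1:8,
            tracking_fraction >= 0, tracking_fraction <= 1)
  if (!is.null(baseline_z)) {
    if (length(baseline_z) == 1) baseline_z <- rep(baseline_z, 8)
    stopifnot(length(baseline_z) == 8, all(baseline_z > 0))
  }
  if (!all(abs(focal_signs) == 1)) {
    stop("focal_signs must be +1 or -1", call. = FALSE)
  }
  structure(list(protocol = protocol,
                 inclusion_sector = as.integer(inclusion_sector),
                 focal_gain = focal_gain, kernel_width = kernel_width,
                 baseline_z = baseline_z, elastance = elastance,
                 drift = drift, noise_sd = noise_sd, artifacts = artifacts,
                 global_gain = global_gain, focal_signs = focal_signs,
                 tracking_fraction = tracking_fraction,
                 osmotic_volume_ml = osmotic_volume_ml,
                 terminal_tau_s = terminal_tau_s,
                 icp_noise_sd = icp_noise_sd,
                 seed = as.integer(seed)),
            class = "bim_scenario")
}

#' Noise level giving a target sample SNR
#'
#' SNR is defined as `20 * log10(mean / sd)`, so the noise standard deviation
#' at a given baseline impedance is `z / 10^(snr_db / 20)`.
#'
#' @param snr_db Target SNR in dB.
#' @param z_ohm Baseline impedance in ohms.
#' @return Noise standard deviation in ohms.
#' @export
#' @examples
#' noise_sd_for_snr(84, 1000)  # ~0.063 ohm
noise_sd_for_snr <- function(snr_db, z_ohm) z_ohm / 10^(snr_db / 20)

#' @export
print.bim_scenario <- function(x, ...) {
  cat("<bim_scenario> focal sector ", x$inclusion_sector,
      ", gain ", x$focal_gain, " ohm/mL, kernel ", x$kernel_width,
      " deg, noise sd ", signif(x$noise_sd, 3), " ohm, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}
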