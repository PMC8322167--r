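# Shared fixture builders. Everything is generated in code; the "tiny"
# protocol keeps the full phase structure but shortens every phase so a
# recording synthesizes in milliseconds.

tiny_protocol <- function() {
  injury_protocol(tibble::tribble(
    ~phase,            ~n_steps, ~step_volume_ml, ~step_interval_s, ~duration_s,
    "baseline",        0L,       0,               0,                1200,
    "inflation",       4L,       0.3,             300,              1200,
    "deflation",       4L,       0.3,             300,              1200,
    "hematoma",        2L,       0.6,             300,              600,
    "global_osmotic",  0L,       0,               0,                600,
    "global_terminal", 0L,       0,               0,                480
  ))
}

# noise-free, drift-free world for exact oracles
clean_scenario <- function(protocol = tiny_protocol(), focal_gain = 30,
                           seed = 1, ...) {
  injury_scenario(protocol = protocol, focal_gain = focal_gain,
                  baseline_z = rep(1000, 8), noise_sd = 0,
                  drift = list(linear_ohm_per_hr = 0,
                               settle_amplitude_ohm = 0, settle_tau_s = 300),
                  icp_noise_sd = 0, seed = seed, ...)
}

# a single-channel trace tibble on a regular grid (no multiplexing; the
# trace-level operations do not require it)
flat_trace <- function(t, z, quality = TRUE) {
  tibble::tibble(t_s = t, z_ohm = z, quality = quality)
}
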