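#' Injury protocol
#'
#' An injury protocol is the ordered schedule of experimental phases applied to
#' one subject: a resting baseline, stepwise balloon inflation modelling a
#' high-impedance (ischemia-like) mass effect, its mirrored deflation, stepwise
#' autologous-blood injection modelling a hemorrhage, a global osmotic-therapy
#' phase, and a global terminal (brain death) phase. Stepped phases change
#' intracranial volume by `step_volume_ml` every `step_interval_s` seconds for
#' `n_steps` steps.
#'
#' The default protocol is: 30 min baseline; inflation in 12 steps of 0.1 mL
#' every 5 min (to 1.2 mL); deflation mirrored over 1 h; hematoma in 6 steps of
#' 0.2 mL every 5 min (to 1.2 mL); 30 min osmotic phase; 15 min terminal phase.
#'
#' @param phases A data frame with columns `phase`, `n_steps`,
#'   `step_volume_ml`, `step_interval_s`, `duration_s`, or `NULL` for the
#'   default protocol. Recognised phase names are `baseline`, `inflation`,
#'   `deflation`, `hematoma`, `global_osmotic`, `global_terminal`.
#' @return A tibble of class `bim_protocol` with one row per phase and an
#'   additional `total_volume_ml` column (`n_steps * step_volume_ml`).
#' @export
#' @examples
#' injury_protocol()
injury_protocol <- function(phases = NULL) {
  if (is.null(phases)) {
    phases <- tibble::tribble(
      ~phase,            ~n_steps, ~step_volume_ml, ~step_interval_s, ~duration_s,
      "baseline",        0L,       0,               0,                1800,
      "inflation",       12L,      0.1,             300,              3600,
      "deflation",       12L,      0.1,             300,              3600,
      "hematoma",        6L,       0.2,             300,              1800,
      "global_osmotic",  0L,       0,               0,                1800,
      "global_terminal", 0L,       0,               0,                900
    )
  }
  phases <- tibble::as_tibble(phases)
  required <- c("phase", "n_steps", "step_volume_ml", "step_interval_s",
                "duration_s")
  missing <- setdiff(required, names(phases))
  if (length(missing) > 0) {
    stop("protocol is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  known <- c("baseline", "inflation", "deflation", "hematoma",
             "global_osmotic", "global_terminal")
  bad <- setdiff(phases$phase, known)
  if (length(bad) > 0) {
    stop("unknown phase name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(phases$phase)) {
    stop("duplicated phase names in protocol", call. = FALSE)
  }
  if (any(phases$step_volume_ml < 0) || any(phases$step_interval_s < 0) ||
      any(phases$duration_s < 0) || any(phases$n_steps < 0)) {
    stop("negative volumes, intervals or durations are not allowed",
         call. = FALSE)
  }
  stepped <- phases$n_steps > 0
  if (any(stepped & phases$step_interval_s <= 0)) {
    stop("stepped phases require step_interval_s > 0", call. = FALSE)
  }
  if (any(stepped & phases$step_volume_ml <= 0)) {
    stop("stepped phases require step_volume_ml > 0", call. = FALSE)
  }
  if (any(stepped &
          phases$duration_s < phases$n_steps * phases$step_interval_s)) {
    stop("phase duration shorter than its step schedule", call. = FALSE)
  }
  phases$n_steps <- as.integer(phases$n_steps)
  phases$total_volume_ml <- phases$n_steps * phases$step_volume_ml
  class(phases) <- c("bim_protocol", class(phases))
  phases
}

#' @rdname injury_protocol
#' @export
default_protocol <- function() injury_protocol()

#' Load an injury protocol from configuration
#'
#' Reads a protocol from a JSON file or an R list. Phases present in the
#' configuration override the corresponding default phase field-for-field;
#' absent phases and absent fields fall back to the defaults of
#' [injury_protocol()]. An empty configuration therefore yields the default
#' protocol.
#'
#' @param config Path to a JSON file, a JSON string, or a named list of
#'   phase overrides, e.g. `list(hematoma = list(n_steps = 3))`.
#' @return A `bim_protocol` tibble.
#' @export
#' @examples
#' load_protocol(list())                       # default protocol
#' load_protocol(list(hematoma = list(n_steps = 3)))  # truncated hematoma
load_protocol <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    stop("config must be a list, JSON string or JSON file path", call. = FALSE)
  }
  proto <- injury_protocol()
  fields <- c("n_steps", "step_volume_ml", "step_interval_s", "duration_s")
  for (ph in names(config)) {
    i <- match(ph, proto$phase)
    if (is.na(i)) stop("unknown phase in config: ", ph, call. = FALSE)
    override <- config[[ph]]
    for (f in intersect(names(override), fields)) {
      proto[[f]][i] <- as.numeric(override[[f]])
    }
    unknown <- setdiff(names(override), fields)
    if (length(unknown) > 0) {
      warning("ignoring unknown protocol field(s) for ", ph, ": ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    # keep duration consistent with an overridden step schedule unless the
    # caller set the duration explicitly
    if (proto$n_steps[i] > 0 && !("duration_s" %in% names(override))) {
      proto$duration_s[i] <- proto$n_steps[i] * proto$step_interval_s[i]
    }
  }
  injury_protocol(proto[, c("phase", "n_steps", "step_volume_ml",
                            "step_interval_s", "duration_s")])
}

#' Phase windows of a protocol
#'
#' @param protocol A `bim_protocol`.
#' @return Tibble with `phase`, `start_s`, `end_s` (seconds from recording
#'   start, t = 0 at start of baseline).
#' @export
protocol_phases <- function(protocol) {
  end <- cumsum(protocol$duration_s)
  tibble::tibble(phase = protocol$phase,
                 start_s = c(0, end[-length(end)]),
                 end_s = end)
}

#' Volume-step schedule of a protocol
#'
#' One row per volume step, with the time the step is applied, the cumulative
#' volume of the phase's mechanism after the step, and the mechanism
#' (`balloon` for inflation/deflation, `blood` for hematoma).
#'
#' @param protocol A `bim_protocol`.
#' @return Tibble with `phase`, `step`, `t_s`, `volume_ml` (cumulative within
#'   mechanism, signed for the balloon), `mechanism`.
#' @export
protocol_steps <- function(protocol) {
  ph <- protocol_phases(protocol)
  rows <- purrr::pmap(protocol, function(phase, n_steps, step_volume_ml,
                                         step_interval_s, duration_s, ...) {
    if (n_steps == 0) return(NULL)
    start <- ph$start_s[ph$phase == phase]
    k <- seq_len(n_steps)
    mech <- if (phase == "hematoma") "blood" else "balloon"
    sign <- if (phase == "deflation") -1 else 1
    tibble::tibble(phase = phase, step = k,
                   t_s = start + (k - 1) * step_interval_s,
                   dv_ml = sign * step_volume_ml, mechanism = mech)
  })
  steps <- dplyr::bind_rows(rows)
  if (nrow(steps) == 0) {
    return(tibble::tibble(phase = character(), step = integer(),
                          t_s = numeric(), dv_ml = numeric(),
                          volume_ml = numeric(), mechanism = character()))
  }
  steps |>
    dplyr::group_by(.data$mechanism) |>
    dplyr::mutate(volume_ml = cumsum(.data$dv_ml)) |>
    dplyr::ungroup()
}

#' Cumulative intracranial volume over time
#'
#' Piecewise-constant balloon and blood volumes implied by the protocol's step
#' schedule, evaluated on an arbitrary time grid. The balloon volume rises
#' during inflation, falls back to zero during deflation; blood volume rises
#' during hematoma and stays (injected blood is not removed).
#'
#' @param protocol A `bim_protocol`.
#' @param t Numeric vector of times in seconds from recording start.
#' @return Tibble with `t_s`, `v_balloon_ml`, `v_blood_ml`, `v_total_ml`.
#' @export
protocol_volume <- function(protocol, t) {
  steps <- protocol_steps(protocol)
  vol_at <- function(mech) {
    s <- steps[steps$mechanism == mech, ]
    if (nrow(s) == 0) return(rep(0, length(t)))
    idx <- findInterval(t, s$t_s)
    c(0, s$volume_ml)[idx + 1]
  }
  vb <- vol_at("balloon")
  vh <- vol_at("blood")
  tibble::tibble(t_s = t, v_balloon_ml = vb, v_blood_ml = vh,
                 v_total_ml = vb + vh)
}

#' @export
print.bim_protocol <- function(x, ...) {
  cat("<bim_protocol> ", nrow(x), " phases, total ",
      sum(x$duration_s) / 60, " min\n", sep = "")
  NextMethod()
}
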