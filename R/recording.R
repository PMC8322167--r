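#' Multichannel bioimpedance recording
#'
#' The pipeline's central object: eight time-multiplexed impedance channels,
#' an ICP series, synchronization events, and metadata. The monitor records
#' one channel at a time for 10 s before switching, so channels cycle
#' 1 through 8 with an 80 s period; each channel's samples therefore occupy
#' only that channel's 10 s slots.
#'
#' @param channels Tibble with columns `channel` (integer 1-8), `t_s`
#'   (seconds from recording start), `z_ohm` (impedance magnitude) and
#'   `quality` (logical, `TRUE` = usable).
#' @param icp Tibble with columns `t_s`, `icp_mmhg`.
#' @param events Tibble with columns `label`, `t_s` and optionally
#'   `duration_s` (NA where not applicable). Labels are structured strings,
#'   e.g. `"phase:inflation"`, `"step:inflation:3"`, `"icc"`, `"ct"`.
#' @param meta Named list; `subject_id`, `seed` and `schema_version` are
#'   conventional.
#' @return An object of class `bim_recording`.
#' @export
bim_recording <- function(channels, icp, events = NULL, meta = list()) {
  if (is.null(events)) {
    events <- tibble::tibble(label = character(), t_s = numeric(),
                             duration_s = numeric())
  }
  if (!"duration_s" %in% names(events)) events$duration_s <- NA_real_
  if (!"quality" %in% names(channels)) channels$quality <- TRUE
  rec <- structure(list(channels = tibble::as_tibble(channels),
                        icp = tibble::as_tibble(icp),
                        events = tibble::as_tibble(events),
                        meta = meta),
                   class = "bim_recording")
  validate_recording(rec)
  rec
}

#' Validate a recording against its type invariants
#'
#' Checks: exactly 8 distinct channel ids in 1-8; strictly increasing
#' timestamps per channel; finite impedance wherever quality is `TRUE`;
#' samples confined to the owning channel's 10 s multiplexing slot; all
#' events within the recording span.
#'
#' @param rec A `bim_recording`.
#' @return `rec`, invisibly; errors describe the first violated invariant.
#' @export
validate_recording <- function(rec) {
  ch <- rec$channels
  ids <- sort(unique(ch$channel))
  if (!identical(as.integer(ids), 1:8)) {
    stop("expected 8 channels with ids 1..8, found: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  for (c_id in 1:8) {
    t_c <- ch$t_s[ch$channel == c_id]
    if (is.unsorted(t_c, strictly = TRUE)) {
      stop("non-monotone timestamps on channel ", c_id, call. = FALSE)
    }
  }
  bad_z <- ch$quality & !is.finite(ch$z_ohm)
  if (any(bad_z)) {
    stop("non-finite impedance flagged usable on channel ",
         ch$channel[which(bad_z)[1]], call. = FALSE)
  }
  slot_ch <- slot_channel(ch$t_s)
  if (any(slot_ch != ch$channel)) {
    i <- which(slot_ch != ch$channel)[1]
    stop("sample at t = ", ch$t_s[i], " s assigned to channel ",
         ch$channel[i], " but lies in channel ", slot_ch[i],
         "'s multiplexing slot", call. = FALSE)
  }
  span <- recording_span(rec)
  ev <- rec$events
  if (nrow(ev) > 0 && (any(ev$t_s < span[1] - 1e-9) ||
                       any(ev$t_s > span[2] + 1e-9))) {
    stop("sync event outside recording span", call. = FALSE)
  }
  invisible(rec)
}

#' Which channel owns the multiplexing slot at time t
#'
#' Channels cycle 1 to 8, 10 s each (80 s period), starting with channel 1 at
#' t = 0.
#'
#' @param t_s Times in seconds.
#' @param slot_s Slot length in seconds (default 10).
#' @param n_channels Number of channels in the cycle (default 8).
#' @return Integer channel ids.
#' @export
slot_channel <- function(t_s, slot_s = 10, n_channels = 8) {
  as.integer(floor((t_s %% (slot_s * n_channels)) / slot_s) + 1)
}

recording_span <- function(rec) {
  t_all <- c(rec$channels$t_s, rec$icp$t_s)
  if (length(t_all) == 0) return(c(0, 0))
  range(t_all)
}

#' @export
print.bim_recording <- function(x, ...) {
  span <- recording_span(x)
  cat("<bim_recording> subject ",
      x$meta$subject_id %||% "?", ": ",
      nrow(x$channels), " impedance samples / 8 channels, ",
      nrow(x$icp), " ICP samples, ",
      nrow(x$events), " events, span ",
      round(diff(span) / 60, 1), " min\n", sep = "")
  invisible(x)
}

#' Write a recording bundle to disk
#'
#' One directory per recording: `channels.csv` (long format: channel, t_s,
#' z_ohm, quality), `icp.csv`, `events.csv`, `meta.json`. Values round-trip
#' through [read_recording()] at full double precision.
#'
#' @param rec A valid `bim_recording`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  readr::write_csv(rec$channels, file.path(path, "channels.csv"))
  readr::write_csv(rec$icp, file.path(path, "icp.csv"))
  readr::write_csv(rec$events, file.path(path, "events.csv"))
  meta <- rec$meta
  if (is.null(meta$schema_version)) meta$schema_version <- 1L
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording bundle from disk
#'
#' Inverse of [write_recording()]. Unknown columns are dropped with a warning;
#' missing required columns are a format error; invariant violations (wrong
#' channel count, non-monotone timestamps) are validation errors.
#'
#' @param path Directory written by [write_recording()].
#' @return A `bim_recording`.
#' @export
read_recording <- function(path) {
  need <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f)) stop("missing file in bundle: ", file, call. = FALSE)
    f
  }
  read_table <- function(file, required, col_types) {
    d <- readr::read_csv(need(file), col_types = col_types,
                         show_col_types = FALSE)
    miss <- setdiff(required, names(d))
    if (length(miss) > 0) {
      stop(file, " is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(d), required)
    if (length(extra) > 0) {
      warning("ignoring unknown column(s) in ", file, ": ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    d[required]
  }
  channels <- read_table("channels.csv",
                         c("channel", "t_s", "z_ohm", "quality"),
                         readr::cols(channel = "i", t_s = "d", z_ohm = "d",
                                     quality = "l", .default = "?"))
  icp <- read_table("icp.csv", c("t_s", "icp_mmhg"),
                    readr::cols(t_s = "d", icp_mmhg = "d", .default = "?"))
  events <- read_table("events.csv", c("label", "t_s", "duration_s"),
                       readr::cols(label = "c", t_s = "d", duration_s = "d",
                                   .default = "?"))
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  bim_recording(channels, icp, events, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
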