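#' Normalize a channel impedance-change vector to 0-1
#'
#' Min-max rescaling of an event's 8-channel impedance-change vector:
#' `ndz_c = (dZ_c - min) / (max - min)`, so the extremes localise a focal
#' injury to a sensitivity sector (the maximum element for a high-impedance
#' injury, the minimum for a low-impedance one). Excluded channels are
#' carried as `NA`.
#'
#' Min-max rescaling is used rather than divide-by-maximum: dividing by the
#' maximum cannot produce 0 for positive vectors and breaks for sign-mixed
#' vectors, while min-max matches the documented 0-1 range.
#'
#' A vector that is flat -- all values equal, or, when `flat_range_ohm > 0`,
#' spanning less than the system's detection resolution -- carries no spatial
#' information: rescaling it would manufacture a full 0-1 spread out of
#' noise. Such maps are returned as all 0.5 with a warning (degenerate map).
#'
#' @param dz Numeric vector of per-channel impedance changes, ohms (NAs
#'   allowed).
#' @param flat_range_ohm Range below which the map is treated as degenerate
#'   (default 0: only exactly-equal values degenerate).
#' @return Vector of the same length with defined values in `[0, 1]` (or all
#'   0.5 when degenerate).
#' @export
#' @examples
#' normalize_deltas(c(4, 2, 1))   # 1, 1/3, 0
normalize_deltas <- function(dz, flat_range_ohm = 0) {
  ok <- is.finite(dz)
  if (sum(ok) < 2) {
    stop("need at least 2 usable channels to normalize", call. = FALSE)
  }
  rng <- range(dz[ok])
  if (diff(rng) <= flat_range_ohm) {
    warning("degenerate map: channel spread ", signif(diff(rng), 3),
            " ohm at or below resolution; returning 0.5", call. = FALSE)
    out <- ifelse(ok, 0.5, NA_real_)
    return(out)
  }
  (dz - rng[1]) / diff(rng)
}

#' Across-subject mean localization map
#'
#' Elementwise mean of per-subject normalized maps, missing-aware, as plotted
#' in cohort colour maps.
#'
#' @param maps Matrix (subjects x 8) or list of length-8 vectors.
#' @return Length-8 vector of mean normalized changes.
#' @export
cohort_mean_map <- function(maps) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  if (is.null(dim(maps))) maps <- matrix(maps, nrow = 1)
  colMeans(maps, na.rm = TRUE)
}

#' Classify an event map as focal or global
#'
#' The heuristic threshold rule: if any element's normalized change falls
#' below 1/3, the event is focal-low-impedance (hemorrhage-like) and the
#' minimum element is the injury element; if any exceeds 2/3, it is
#' focal-high-impedance (model ischemia) at the maximum element; if all
#' values lie strictly within (1/3, 2/3), the event is global. A degenerate
#' all-0.5 map is global.
#'
#' When both thresholds are satisfied -- the common case for min-max maps,
#' which pin one element to 0 and one to 1 -- the focal element is the
#' extreme that is isolated from the bulk of the map: if the map's median
#' lies below 0.5 the bulk sits low and the high outlier is focal
#' (focal_high_z), and vice versa. With an exactly central median the larger
#' deviation from 0.5 wins.
#'
#' @param mean_map Length-8 numeric map (NAs allowed; >= 2 defined values).
#' @param lo,hi Classification thresholds (defaults 1/3 and 2/3).
#' @return One-row tibble: `label` (`"focal_high_z"`, `"focal_low_z"` or
#'   `"global"`) and `element` (channel id, NA for global).
#' @export
classify_event <- function(mean_map, lo = 1/3, hi = 2/3) {
  ok <- is.finite(mean_map)
  if (sum(ok) < 2) stop("need at least 2 defined elements", call. = FALSE)
  mn <- min(mean_map, na.rm = TRUE)
  mx <- max(mean_map, na.rm = TRUE)
  low <- mn < lo
  high <- mx > hi
  if (low && high) {
    skew <- stats::median(mean_map, na.rm = TRUE) - 0.5
    if (skew < 0) {
      low <- FALSE            # bulk low, high outlier is the injury element
    } else if (skew > 0) {
      high <- FALSE           # bulk high, low outlier is the injury element
    } else if ((0.5 - mn) >= (mx - 0.5)) {
      high <- FALSE
    } else {
      low <- FALSE
    }
  }
  if (low) {
    tibble::tibble(label = "focal_low_z",
                   element = which.min(mean_map))
  } else if (high) {
    tibble::tibble(label = "focal_high_z",
                   element = which.max(mean_map))
  } else {
    tibble::tibble(label = "global", element = NA_integer_)
  }
}

#' Localize every event of a cohort
#'
#' Builds per-subject normalized maps from cohort channel metrics, averages
#' them across subjects per event, and classifies each event with the
#' threshold rule. Classification runs on the cohort mean map by default
#' (matching cohort colour-map analysis); `per_subject = TRUE` additionally
#' classifies each subject's own map, the single-patient mode.
#'
#' @param channel_metrics Tibble with columns `subject`, `phase`, `channel`,
#'   `delta_z` (as from [analyze_cohort()]'s metrics).
#' @param flat_range_ohm Degeneracy floor forwarded to [normalize_deltas()]
#'   (default 7.1, the detection resolution).
#' @param per_subject Also classify per-subject maps (default FALSE).
#' @return List of class `bim_localization`: `maps` (tibble `phase`,
#'   `channel`, `mean_ndz`), `classification` (tibble `phase`, `label`,
#'   `element`), and optionally `subject_classification`.
#' @export
localize_events <- function(channel_metrics, flat_range_ohm = 7.1,
                            per_subject = FALSE) {
  ndz_of <- function(d) {
    dz <- d$delta_z[match(1:8, d$channel)]
    suppressWarnings(normalize_deltas(dz, flat_range_ohm = flat_range_ohm))
  }
  phases <- unique(channel_metrics$phase)
  maps <- list(); cls <- list(); subj_cls <- list()
  for (phase in phases) {
    d_ph <- channel_metrics[channel_metrics$phase == phase, ]
    subj_maps <- lapply(split(d_ph, d_ph$subject), ndz_of)
    mm <- cohort_mean_map(subj_maps)
    maps[[phase]] <- tibble::tibble(phase = phase, channel = 1:8,
                                    mean_ndz = mm)
    cls[[phase]] <- dplyr::mutate(classify_event(mm), phase = phase,
                                  .before = 1)
    if (per_subject) {
      subj_cls[[phase]] <- dplyr::bind_rows(lapply(names(subj_maps),
        function(s) {
          dplyr::mutate(classify_event(subj_maps[[s]]), subject = s,
                        phase = phase, .before = 1)
        }))
    }
  }
  out <- list(maps = dplyr::bind_rows(maps),
              classification = dplyr::bind_rows(cls))
  if (per_subject) out$subject_classification <- dplyr::bind_rows(subj_cls)
  structure(out, class = "bim_localization")
}

#' @export
print.bim_localization <- function(x, ...) {
  cat("<bim_localization>\n")
  print(x$classification)
  invisible(x)
}
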