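#' Construct a session log
#'
#' Bundles the multimodal streams of one participant's session: the gaze
#' stream (timestamped unit gaze directions plus head position), driving
#' telemetry (speed, brake), button presses, the change-event schedule, the
#' time-indexed AOI geometry, and per-complexity segment bounds. The object
#' is validated on construction (see [validate_session()]).
#'
#' @param participant_id Character id.
#' @param group Experimental group `"A"`, `"B"` or `"C"`.
#' @param gaze Tibble with columns `t, gx, gy, gz, hx, hy, hz, valid`.
#' @param driving Tibble with columns `t, speed_kmh, brake`.
#' @param presses Tibble with columns `t, side` (`"left"` or `"right"`).
#' @param events Change events as from [build_schedule()].
#' @param aois Named list of AOIs; each a list with `aoi_id`, `kind`
#'   (`"agent"` or `"object"`), `radius` (metres), and `track` (tibble
#'   `t, x, y, z`).
#' @param segment_bounds Tibble `complexity, start_t, end_t` partitioning the
#'   session into the three complexity segments.
#' @param meta Named list of additional metadata (seed, generator version,
#'   `speed_limit_kmh`, ...).
#' @param validate Run [validate_session()] before returning (default TRUE).
#' @return An object of class `cb_session`.
#' @export
session_log <- function(participant_id, group, gaze, driving, presses,
                        events, aois, segment_bounds, meta = list(),
                        validate = TRUE) {
  s <- structure(
    list(
      participant_id = participant_id,
      group = group,
      gaze = tibble::as_tibble(gaze),
      driving = tibble::as_tibble(driving),
      presses = tibble::as_tibble(presses),
      events = strip_schedule_attrs(tibble::as_tibble(events)),
      aois = aois,
      segment_bounds = tibble::as_tibble(segment_bounds),
      meta = meta
    ),
    class = "cb_session"
  )
  if (validate) validate_session(s)
  s
}

# events are stored as a plain tibble; the schedule's carrier attributes
# live on the session itself (segment_bounds) or its metadata
strip_schedule_attrs <- function(events) {
  attr(events, "segment_bounds") <- NULL
  attr(events, "group") <- NULL
  class(events) <- setdiff(class(events), "cb_schedule")
  events
}

empty_gaze <- function() {
  tibble::tibble(
    t = numeric(), gx = numeric(), gy = numeric(), gz = numeric(),
    hx = numeric(), hy = numeric(), hz = numeric(), valid = logical()
  )
}

empty_driving <- function() {
  tibble::tibble(t = numeric(), speed_kmh = numeric(), brake = logical())
}

empty_presses <- function() {
  tibble::tibble(t = numeric(), side = character())
}

#' Validate a session log
#'
#' Checks every type invariant of the session: strictly increasing
#' timestamps in each stream, unit-norm gaze directions for valid samples,
#' non-negative speed within the configured limit, legal press sides,
#' well-formed change pairs whose `aoi_id` resolves and whose AOI track
#' covers the event-aligned analysis window, and segment bounds that
#' partition the session in the group's complexity order. Errors name the
#' offending record.
#'
#' @param session A `cb_session`.
#' @return Invisibly `TRUE`; otherwise a classed validation error.
#' @export
validate_session <- function(session) {
  if (!inherits(session, "cb_session")) {
    abort_argument("session must be a cb_session")
  }
  g <- session$gaze
  if (nrow(g) > 0) {
    if (!is_strictly_increasing(g$t)) {
      abort_validation(sprintf(
        "gaze timestamps are not strictly increasing at row %d",
        first_violation_index(g$t)
      ))
    }
    vr <- which(g$valid)
    if (length(vr)) {
      nrm <- sqrt(g$gx[vr]^2 + g$gy[vr]^2 + g$gz[vr]^2)
      bad <- which(abs(nrm - 1) > 1e-6)
      if (length(bad)) {
        abort_validation(sprintf(
          "gaze direction at row %d is not a unit vector (norm %.8f)",
          vr[bad[1]], nrm[bad[1]]
        ))
      }
    }
  }

  d <- session$driving
  if (nrow(d) > 0) {
    if (!is_strictly_increasing(d$t)) {
      abort_validation(sprintf(
        "driving timestamps are not strictly increasing at row %d",
        first_violation_index(d$t)
      ))
    }
    limit <- session$meta$speed_limit_kmh %||% SPEED_LIMIT_KMH
    bad <- which(d$speed_kmh < 0 | d$speed_kmh > limit + 2)
    if (length(bad)) {
      abort_validation(sprintf(
        "speed at driving row %d (%.2f km/h) is outside [0, limit + 2]",
        bad[1], d$speed_kmh[bad[1]]
      ))
    }
  }

  p <- session$presses
  if (nrow(p) > 0) {
    bad <- which(!p$side %in% c("left", "right"))
    if (length(bad)) {
      abort_validation(sprintf(
        "press at row %d has side '%s' (must be left or right)",
        bad[1], p$side[bad[1]]
      ))
    }
  }

  ev <- session$events
  if (nrow(ev) > 0) {
    bad <- which(!ev$change_type %in% CHANGE_TYPES)
    if (length(bad)) {
      abort_validation(sprintf(
        "event %s has unknown change_type '%s'",
        ev$change_id[bad[1]], ev$change_type[bad[1]]
      ))
    }
    missing_aoi <- setdiff(ev$aoi_id, names(session$aois))
    if (length(missing_aoi)) {
      abort_validation(sprintf(
        "event references unknown aoi_id '%s'", missing_aoi[1]
      ))
    }
    for (pid in unique(ev$pair_id)) {
      pr <- ev[ev$pair_id == pid, ]
      if (nrow(pr) != 2 || sum(pr$change_type == "property") != 1) {
        abort_validation(sprintf(
          "pair %s must hold exactly one behaviour and one property change",
          pid
        ))
      }
      b <- pr[pr$change_type != "property", ]
      q <- pr[pr$change_type == "property", ]
      if (b$trigger_t > q$trigger_t + 1e-9) {
        abort_validation(sprintf(
          "pair %s: behaviour change must precede the property change", pid
        ))
      }
      if (abs((q$trigger_t - b$trigger_t) - pr$gap_s[1]) > 1e-6) {
        abort_validation(sprintf(
          "pair %s: trigger difference does not equal gap_s", pid
        ))
      }
    }
    for (i in seq_len(nrow(ev))) {
      a <- session$aois[[ev$aoi_id[i]]]
      if (a$radius <= 0) {
        abort_validation(sprintf("AOI %s has non-positive radius", a$aoi_id))
      }
      if (!is_strictly_increasing(a$track$t)) {
        abort_validation(sprintf(
          "AOI %s track timestamps are not strictly increasing", a$aoi_id
        ))
      }
      if (min(a$track$t) > ev$trigger_t[i] - 4 + 1e-9 ||
          max(a$track$t) < ev$trigger_t[i] + 4 - 1e-9) {
        abort_validation(sprintf(
          "AOI %s track does not cover [trigger - 4 s, trigger + 4 s] of %s",
          a$aoi_id, ev$change_id[i]
        ))
      }
    }
  }

  sb <- session$segment_bounds
  if (nrow(sb) > 0) {
    if (any(abs(sb$start_t[-1] - sb$end_t[-nrow(sb)]) > 1e-9)) {
      abort_validation("segment bounds do not partition the session")
    }
    if (!identical(sb$complexity, complexity_order(session$group))) {
      abort_validation(sprintf(
        "segment order %s does not match group %s",
        paste(sb$complexity, collapse = "-"), session$group
      ))
    }
    if (nrow(ev) > 0) {
      seg_of <- segment_index_at(sb, ev$trigger_t)
      if (anyNA(seg_of)) {
        abort_validation("an event trigger falls outside the segment bounds")
      }
    }
  }
  invisible(TRUE)
}

# index of the segment containing each time (NA when outside); half-open
segment_index_at <- function(segment_bounds, t) {
  idx <- rep(NA_integer_, length(t))
  for (i in seq_len(nrow(segment_bounds))) {
    inside <- t >= segment_bounds$start_t[i] - 1e-9 &
      t < segment_bounds$end_t[i] + 1e-9
    idx[inside & is.na(idx)] <- i
  }
  idx
}

#' @export
print.cb_session <- function(x, ...) {
  cat(sprintf(
    "<cb_session> participant %s (group %s): %d gaze samples, %d driving samples, %d presses, %d changes, %d AOIs\n",
    x$participant_id, x$group, nrow(x$gaze), nrow(x$driving),
    nrow(x$presses), nrow(x$events), length(x$aois)
  ))
  invisible(x)
}
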