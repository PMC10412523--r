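#' Dwell of fixations on a dynamic 3D area of interest
#'
#' A fixation "lands" on the AOI when the angle between its centroid gaze
#' direction and the head-to-AOI-centre direction (the centre linearly
#' interpolated at the fixation midpoint, the head position interpolated
#' from the gaze stream) is at most `atan(radius / distance)`. Saccade
#' (non-fixation) samples never contribute. Returns the landing fixations'
#' sub-intervals clipped to the analysis window.
#'
#' @param fixations Fixation table from [detect_fixations()].
#' @param gaze The gaze stream the fixations came from (supplies the head
#'   position; an empty stream implies a head at the origin).
#' @param aoi An AOI record (list with `aoi_id`, `radius`, `track`).
#' @param window Numeric length-2, the half-open analysis window `[a, b)`;
#'   must be covered by the AOI track.
#' @return Tibble `start_t, end_t` of clipped on-AOI intervals.
#' @export
aoi_dwell <- function(fixations, gaze, aoi, window) {
  if (length(window) != 2 || window[2] <= window[1]) {
    abort_argument("window must be an increasing length-2 numeric")
  }
  if (window[1] < min(aoi$track$t) - 1e-9 ||
      window[2] > max(aoi$track$t) + 1e-9) {
    abort_coverage(sprintf(
      "window [%.2f, %.2f) is outside AOI %s track coverage [%.2f, %.2f]",
      window[1], window[2], aoi$aoi_id, min(aoi$track$t), max(aoi$track$t)
    ))
  }
  empty <- tibble::tibble(start_t = numeric(), end_t = numeric())
  if (nrow(fixations) == 0) return(empty)
  fx <- fixations[fixations$end_t > window[1] &
    fixations$start_t < window[2], , drop = FALSE]
  if (nrow(fx) == 0) return(empty)

  mid <- (fx$start_t + fx$end_t) / 2
  # head interpolation only needs the stream near the window
  gz <- if (nrow(gaze)) {
    gaze[gaze$t >= min(mid) - 1 & gaze$t <= max(mid) + 1, , drop = FALSE]
  } else {
    gaze
  }
  h <- if (nrow(gz) < 2) {
    matrix(0, length(mid), 3)
  } else {
    cbind(
      approx(gz$t, gz$hx, mid, rule = 2)$y,
      approx(gz$t, gz$hy, mid, rule = 2)$y,
      approx(gz$t, gz$hz, mid, rule = 2)$y
    )
  }
  ctr <- t(vapply(mid, function(tt) interp_track(aoi$track, tt),
    numeric(3)))
  rel <- ctr - h
  dist <- sqrt(rowSums(rel * rel))
  ang_thr <- rad2deg(atan(aoi$radius / dist))
  cdir <- cbind(fx$cx, fx$cy, fx$cz)
  ang <- rad2deg(acos(clamp(rowSums(unit_rows(rel) * cdir), -1, 1)))
  hit <- ang <= ang_thr
  if (!any(hit)) return(empty)
  tibble::tibble(
    start_t = pmax(fx$start_t[hit], window[1]),
    end_t = pmin(fx$end_t[hit], window[2])
  )
}

#' Event-aligned dwell time-course
#'
#' Apportions on-AOI dwell to eight half-open 1 s bins spanning
#' `[trigger - 4 s, trigger + 4 s)`, in milliseconds per bin.
#'
#' @inheritParams aoi_dwell
#' @param event One change-event row (with `change_id` and `trigger_t`).
#' @param half_width_s Half-width of the analysis window (default 4 s).
#' @return List of class `cb_timecourse` with `change_id`, `bins` (named
#'   vector of 2 * `half_width_s` dwell values, ms), `dwell_pre_ms`,
#'   `dwell_post_ms`.
#' @export
event_timecourse <- function(fixations, gaze, event, aoi,
                             half_width_s = 4) {
  trig <- event$trigger_t
  window <- c(trig - half_width_s, trig + half_width_s)
  iv <- aoi_dwell(fixations, gaze, aoi, window)
  edges <- trig + seq(-half_width_s, half_width_s, by = 1)
  nb <- length(edges) - 1L
  bins <- vapply(seq_len(nb), function(b) {
    1000 * sum(interval_overlap(iv$start_t, iv$end_t,
      edges[b], edges[b + 1]))
  }, numeric(1))
  names(bins) <- sprintf("[%+d,%+d)", seq(-half_width_s, half_width_s - 1),
    seq(-half_width_s + 1, half_width_s))
  structure(
    list(
      change_id = event$change_id,
      bins = bins,
      dwell_pre_ms = sum(bins[seq_len(nb / 2)]),
      dwell_post_ms = sum(bins[seq_len(nb / 2) + nb / 2])
    ),
    class = "cb_timecourse"
  )
}

# dwell (ms) of clipped on-AOI intervals inside [a, b)
dwell_in_ms <- function(intervals, a, b) {
  1000 * sum(interval_overlap(intervals$start_t, intervals$end_t, a, b))
}
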