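#' Generative parameters of a synthetic participant
#'
#' Collects every behavioural regularity the simulator reproduces: detection
#' probabilities per change type and complexity (weakly decreasing in
#' complexity under the defaults), a positively skewed reaction-time law, a
#' probability of pressing the wrong-side button, a false-alarm rate,
#' pre/post-change AOI gaze probabilities per change type (with anticipatory
#' onsets for behaviour-relevant changes and post-change lingering for
#' detected property changes), a baseline fixation renewal process per
#' complexity, per-complexity driving profiles, and a per-encounter learning
#' increment on property-change detection.
#'
#' @param p_detect 3x3 numeric matrix, rows `behaviour_relevant`,
#'   `behaviour_irrelevant`, `property`; columns `low`, `medium`, `high`;
#'   probabilities of detecting a change of that cell.
#' @param rt_meanlog,rt_sdlog Lognormal parameters of the reaction time in
#'   seconds; the defaults give a realised mean + 3 SD near 4 s.
#' @param rt_max_s Truncation bound of the RT law (default 10 s).
#' @param wrong_button_p Probability a detection is registered on the wrong
#'   side.
#' @param false_alarm_rate_per_min Homogeneous rate of spurious presses.
#' @param p_gaze_pre,p_gaze_post Named vectors (per change type) of the
#'   probability that an AOI dwell of at least 100 ms occurs in the 4 s
#'   pre/post window of a change.
#' @param anticipatory_lead_s Seconds before a behaviour-relevant change at
#'   which the pre-change AOI gaze onset concentrates.
#' @param linger_extra_s Extra AOI dwell (seconds), placed about 3 s after
#'   the change, for detected property changes.
#' @param fixation_rate_hz Named vector (per complexity) of baseline
#'   fixations per second.
#' @param fix_dur_meanlog,fix_dur_sdlog Lognormal parameters of fixation
#'   duration (seconds), truncated to `[0.1, 0.5]`.
#' @param speed_kmh Named vector of mean driving speed per complexity.
#' @param brake_rate_per_min Named vector of brake-press events per minute
#'   per complexity.
#' @param learning_slope Per-encounter increment applied to
#'   `p_detect["property", ]`.
#' @param gaze_jitter Standard deviation (per axis) of the additive gaze
#'   direction noise within a fixation; 5e-4 corresponds to roughly 0.04
#'   degrees of angular jitter.
#' @return An object of class `cb_driver_params`.
#' @seealso [default_params()], [simulate_session()]
#' @export
driver_params <- function(
    p_detect = default_p_detect(),
    rt_meanlog = -0.15, rt_sdlog = 0.75, rt_max_s = 10,
    wrong_button_p = 0.02,
    false_alarm_rate_per_min = 0.3,
    p_gaze_pre = c(behaviour_relevant = 0.85, behaviour_irrelevant = 0.55,
      property = 0.50),
    p_gaze_post = c(behaviour_relevant = 0.75, behaviour_irrelevant = 0.65,
      property = 0.70),
    anticipatory_lead_s = 1.5,
    linger_extra_s = 0.3,
    fixation_rate_hz = c(low = 3.57, medium = 2.93, high = 3.18),
    fix_dur_meanlog = log(0.25), fix_dur_sdlog = 0.3,
    speed_kmh = c(low = 26, medium = 25, high = 18),
    brake_rate_per_min = c(low = 8, medium = 6, high = 4),
    learning_slope = 0.002,
    gaze_jitter = 5e-4) {
  p_detect <- as.matrix(p_detect)
  if (!identical(rownames(p_detect), CHANGE_TYPES) ||
      !identical(colnames(p_detect), COMPLEXITY_LEVELS)) {
    abort_argument(
      "p_detect must have rows behaviour_relevant/behaviour_irrelevant/property and columns low/medium/high"
    )
  }
  probs <- c(p_detect, p_gaze_pre, p_gaze_post, wrong_button_p)
  if (any(probs < 0 | probs > 1)) {
    abort_argument("all probabilities must lie in [0, 1]")
  }
  if (any(!CHANGE_TYPES %in% names(p_gaze_pre)) ||
      any(!CHANGE_TYPES %in% names(p_gaze_post))) {
    abort_argument("p_gaze_pre/p_gaze_post must be named by change type")
  }
  if (any(!COMPLEXITY_LEVELS %in% names(fixation_rate_hz)) ||
      any(!COMPLEXITY_LEVELS %in% names(speed_kmh)) ||
      any(!COMPLEXITY_LEVELS %in% names(brake_rate_per_min))) {
    abort_argument("per-complexity parameters must be named low/medium/high")
  }
  if (rt_max_s <= 0 || false_alarm_rate_per_min < 0 ||
      any(fixation_rate_hz <= 0) || any(speed_kmh < 0) ||
      any(brake_rate_per_min < 0)) {
    abort_argument("rates and bounds must be non-negative (rt_max_s > 0)")
  }
  structure(
    list(
      p_detect = p_detect,
      rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog, rt_max_s = rt_max_s,
      wrong_button_p = wrong_button_p,
      false_alarm_rate_per_min = false_alarm_rate_per_min,
      p_gaze_pre = p_gaze_pre[CHANGE_TYPES],
      p_gaze_post = p_gaze_post[CHANGE_TYPES],
      anticipatory_lead_s = anticipatory_lead_s,
      linger_extra_s = linger_extra_s,
      fixation_rate_hz = fixation_rate_hz[COMPLEXITY_LEVELS],
      fix_dur_meanlog = fix_dur_meanlog, fix_dur_sdlog = fix_dur_sdlog,
      speed_kmh = speed_kmh[COMPLEXITY_LEVELS],
      brake_rate_per_min = brake_rate_per_min[COMPLEXITY_LEVELS],
      learning_slope = learning_slope,
      gaze_jitter = gaze_jitter
    ),
    class = "cb_driver_params"
  )
}

default_p_detect <- function() {
  m <- rbind(
    behaviour_relevant   = c(low = 0.680, medium = 0.641, high = 0.551),
    behaviour_irrelevant = c(low = 0.650, medium = 0.602, high = 0.375),
    property             = c(low = 0.600, medium = 0.530, high = 0.380)
  )
  colnames(m) <- COMPLEXITY_LEVELS
  m
}

#' Default synthetic-driver parameters
#'
#' The default detection matrix decreases with complexity within every change
#' type, declines fastest for behaviour-irrelevant changes between the medium
#' and high levels, and yields a cohort-level detection rate in the mid-50s
#' percent; the RT law puts the realised mean + 3 SD near 4 s. See the
#' methods vignette for the provenance of each default.
#'
#' @return A `cb_driver_params` object.
#' @export
#' @examples
#' p <- default_params()
#' p$p_detect
default_params <- function() driver_params()

#' @export
print.cb_driver_params <- function(x, ...) {
  cat("<cb_driver_params>\n  p_detect:\n")
  print(round(x$p_detect, 3))
  cat(sprintf(
    "  RT ~ lognormal(%.2f, %.2f) truncated at %.1f s; wrong button %.1f%%; false alarms %.2f/min\n",
    x$rt_meanlog, x$rt_sdlog, x$rt_max_s, 100 * x$wrong_button_p,
    x$false_alarm_rate_per_min
  ))
  invisible(x)
}
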