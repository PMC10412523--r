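# Derived event metrics: gaze categories, LBFTS classification, detection
# rate-of-change slopes, driving metrics, temporal proximity and learning
# effect tables.

#' LBFTS classification windows
#'
#' Configuration of the looked-but-failed-to-see criteria: the pre/post
#' change windows (seconds) and the minimum AOI dwell (milliseconds) that
#' counts as "having gazed". The default is 4 s before and 4 s after with a
#' 100 ms dwell threshold; a 2 s pre-window is the usual robustness
#' alternative.
#'
#' @param pre_window_s,post_window_s Window widths in seconds (positive).
#' @param min_dwell_ms Dwell threshold in milliseconds.
#' @return Object of class `cb_lbfts_config`.
#' @export
lbfts_config <- function(pre_window_s = 4, post_window_s = 4,
                         min_dwell_ms = 100) {
  if (pre_window_s <= 0 || post_window_s <= 0 || min_dwell_ms <= 0) {
    abort_argument("LBFTS windows and dwell threshold must be positive")
  }
  if (min_dwell_ms > 1000 * min(pre_window_s, post_window_s)) {
    abort_argument("min_dwell_ms cannot exceed the shorter window")
  }
  structure(
    list(pre_window_s = pre_window_s, post_window_s = post_window_s,
      min_dwell_ms = min_dwell_ms),
    class = "cb_lbfts_config"
  )
}

#' Gaze category of a change
#'
#' Classifies each change by where AOI dwell reached the threshold:
#' `"both"` when pre- and post-change dwell are both at least
#' `min_dwell_ms`, else `"before_only"`, `"after_only"` or `"none"`.
#'
#' @param dwell_pre_ms,dwell_post_ms Non-negative dwell (ms) in the pre and
#'   post windows; vectorised.
#' @param min_dwell_ms Threshold in milliseconds (default 100).
#' @return Character vector of categories.
#' @export
#' @examples
#' gaze_category(c(150, 150, 0), c(150, 50, 0))
gaze_category <- function(dwell_pre_ms, dwell_post_ms, min_dwell_ms = 100) {
  if (any(dwell_pre_ms < 0, na.rm = TRUE) ||
      any(dwell_post_ms < 0, na.rm = TRUE)) {
    abort_argument("dwell times must be non-negative")
  }
  pre <- dwell_pre_ms >= min_dwell_ms
  post <- dwell_post_ms >= min_dwell_ms
  dplyr::case_when(
    pre & post ~ "both",
    pre & !post ~ "before_only",
    !pre & post ~ "after_only",
    TRUE ~ "none"
  )
}

#' Classify looked-but-failed-to-see errors
#'
#' A change is an LBFTS error when it was not detected although the
#' participant gazed at its AOI for at least the dwell threshold in both
#' the pre- and the post-change window.
#'
#' @param detected Logical; vectorised.
#' @param dwell_pre_ms,dwell_post_ms Dwell (ms) measured under the
#'   configured windows.
#' @param config An [lbfts_config()].
#' @return Logical vector.
#' @export
classify_lbfts <- function(detected, dwell_pre_ms, dwell_post_ms,
                           config = lbfts_config()) {
  cat <- gaze_category(dwell_pre_ms, dwell_post_ms, config$min_dwell_ms)
  !detected & cat == "both"
}

#' LBFTS rate table
#'
#' Per change type x complexity cell: the LBFTS count, the number of
#' both-window gazers, the number of changes, and the LBFTS rate under both
#' denominators (`rate_gazers_pct`, the default reading, and
#' `rate_all_pct`). Cells with an empty denominator report `NA`, never 0/0.
#'
#' @param outcomes Outcome table with `lbfts`, `gaze_category`,
#'   `change_type`, `complexity`.
#' @param group_by Grouping columns (default change type x complexity).
#' @return Tibble of per-cell counts and rates.
#' @export
lbfts_table <- function(outcomes,
                        group_by = c("change_type", "complexity")) {
  if (nrow(outcomes) == 0) abort_argument("outcomes must be non-empty")
  outcomes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_lbfts = sum(.data$lbfts, na.rm = TRUE),
      n_gazers = sum(.data$gaze_category == "both", na.rm = TRUE),
      n_all = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate_gazers_pct = ifelse(.data$n_gazers > 0,
        100 * .data$n_lbfts / .data$n_gazers, NA_real_),
      rate_all_pct = ifelse(.data$n_all > 0,
        100 * .data$n_lbfts / .data$n_all, NA_real_)
    )
}

#' Rate-of-change slopes across complexity levels
#'
#' Percentage-point differences of a detection rate between adjacent
#' complexity levels: `medium - low` and `high - medium`, plus their mean.
#' (A ratio variant, `100 * (rate2 / rate1 - 1)`, is available via
#' `as_ratio = TRUE` but is not the default reading.)
#'
#' @param rates_by_complexity Numeric vector of rates (percent) named or
#'   ordered `low`, `medium`, `high`.
#' @param as_ratio Use the ratio variant instead of differences.
#' @return Tibble `slope_low_medium`, `slope_medium_high`, `mean_slope`.
#' @export
#' @examples
#' roc_slopes(c(low = 60, medium = 56.1, high = 47.08))
roc_slopes <- function(rates_by_complexity, as_ratio = FALSE) {
  r <- rates_by_complexity
  if (!is.null(names(r))) {
    if (!all(COMPLEXITY_LEVELS %in% names(r))) {
      abort_argument("rates must cover levels low, medium, high")
    }
    r <- r[COMPLEXITY_LEVELS]
  }
  if (length(r) != 3 || anyNA(r)) {
    abort_argument("rates must be three non-missing values (low, medium, high)")
  }
  s1 <- if (as_ratio) 100 * (r[[2]] / r[[1]] - 1) else r[[2]] - r[[1]]
  s2 <- if (as_ratio) 100 * (r[[3]] / r[[2]] - 1) else r[[3]] - r[[2]]
  tibble::tibble(
    slope_low_medium = s1, slope_medium_high = s2,
    mean_slope = (s1 + s2) / 2
  )
}

#' Driving metrics per complexity segment
#'
#' For each complexity segment: the time-weighted average speed, the
#' completion time in minutes (segment duration), and the number of brake
#' hits (rising edges of the brake signal).
#'
#' @param driving Driving stream (`t`, `speed_kmh`, `brake`).
#' @param segment_bounds Tibble `complexity, start_t, end_t`.
#' @return Tibble `complexity, avg_speed_kmh, completion_min, brake_hits`;
#'   segments without samples carry `NA` speed and hits.
#' @export
driving_metrics <- function(driving, segment_bounds) {
  rows <- lapply(seq_len(nrow(segment_bounds)), function(i) {
    a <- segment_bounds$start_t[i]
    b <- segment_bounds$end_t[i]
    d <- driving[driving$t >= a & driving$t < b, , drop = FALSE]
    if (nrow(d) == 0) {
      return(tibble::tibble(
        complexity = segment_bounds$complexity[i],
        avg_speed_kmh = NA_real_, completion_min = (b - a) / 60,
        brake_hits = NA_integer_
      ))
    }
    # weight each sample by its holding time up to the next sample
    w <- diff(c(d$t, b))
    avg <- sum(d$speed_kmh * w) / sum(w)
    hits <- sum(diff(c(FALSE, d$brake)) == 1)
    tibble::tibble(
      complexity = segment_bounds$complexity[i],
      avg_speed_kmh = avg, completion_min = (b - a) / 60,
      brake_hits = as.integer(hits)
    )
  })
  dplyr::bind_rows(rows)
}

#' Property-change detection by temporal proximity
#'
#' Detection rate of property changes at each of the six design gap levels
#' (0, 1, 2, 4, 6, 8 s from the paired behaviour change). Always returns
#' exactly six rows; a per-participant mean table for downstream ANOVA is
#' attached as attribute `"per_participant"`.
#'
#' @param outcomes Outcome table carrying `change_type`, `gap_s`, `detected`
#'   (and `participant_id` for the per-participant table).
#' @return Tibble `gap_s, n, n_detected, rate_pct` (six rows).
#' @export
temporal_proximity_table <- function(outcomes) {
  prop <- outcomes[outcomes$change_type == "property", , drop = FALSE]
  bad <- setdiff(unique(prop$gap_s), GAP_LEVELS_S)
  if (length(bad)) {
    abort_validation(sprintf("unknown gap level(s): %s",
      paste(bad, collapse = ", ")))
  }
  tab <- prop |>
    dplyr::group_by(gap_s = factor(.data$gap_s, levels = GAP_LEVELS_S),
      .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(), n_detected = sum(.data$detected), .groups = "drop"
    ) |>
    dplyr::mutate(
      gap_s = as.numeric(as.character(.data$gap_s)),
      rate_pct = ifelse(.data$n > 0, 100 * .data$n_detected / .data$n,
        NA_real_)
    )
  if ("participant_id" %in% names(prop)) {
    attr(tab, "per_participant") <- prop |>
      dplyr::group_by(.data$participant_id, .data$gap_s) |>
      dplyr::summarise(rate_pct = 100 * mean(.data$detected),
        .groups = "drop")
  }
  tab
}

#' First-versus-last segment learning comparison
#'
#' Compares each participant's first complexity segment against the third
#' (the session's route has exactly three blocks), per change type, on two
#' metrics: detection rate and mean AOI dwell (pre + post). The paired test
#' itself is delegated to [paired_t()]; per-participant values are attached
#' as attribute `"per_participant"`.
#'
#' @param outcomes Outcome table carrying `participant_id`,
#'   `encounter_index`, `change_type`, `detected` and (optionally) dwell
#'   columns.
#' @param n_changes_per_segment Changes per complexity segment (default 24).
#' @return Tibble per change type with first/last detection rates and mean
#'   dwells.
#' @export
learning_effect <- function(outcomes, n_changes_per_segment = 24) {
  seg <- (outcomes$encounter_index - 1) %/% n_changes_per_segment + 1
  if (max(seg) < 3) {
    abort_validation("outcomes must span three complexity segments")
  }
  oc <- outcomes[seg %in% c(1, 3), , drop = FALSE]
  oc$session_half <- ifelse(
    (oc$encounter_index - 1) %/% n_changes_per_segment + 1 == 1,
    "first", "last"
  )
  has_dwell <- all(c("dwell_pre_ms", "dwell_post_ms") %in% names(oc))
  per <- oc |>
    dplyr::group_by(.data$participant_id, .data$change_type,
      .data$session_half) |>
    dplyr::summarise(
      rate_pct = 100 * mean(.data$detected),
      dwell_ms = if (has_dwell) {
        mean(.data$dwell_pre_ms + .data$dwell_post_ms)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  summary <- per |>
    dplyr::group_by(.data$change_type, .data$session_half) |>
    dplyr::summarise(
      rate_pct = mean(.data$rate_pct),
      dwell_ms = mean(.data$dwell_ms),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "session_half",
      values_from = c("rate_pct", "dwell_ms")
    )
  attr(summary, "per_participant") <- per
  summary
}
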