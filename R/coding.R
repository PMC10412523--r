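# Response coding: C1 (side must match the change type: right button for
# behaviour changes, left for property changes) and C2 (the press must occur
# before the next change requiring the same side), screened by a reaction
# time cutoff of mean + 3 SD pooled across the cohort.

#' Reaction-time cutoff
#'
#' In `"derived"` mode the cutoff is the mean plus three sample standard
#' deviations (n - 1 denominator) of the supplied matched reaction times,
#' pooled across subjects and conditions. `"fixed"` returns the supplied
#' value, `"paper_default"` the conventional 4.1 s window for this paradigm.
#' When `presses` and `events` are supplied, every press is re-screened
#' against the cutoff and the inside/outside percentages are reported (a
#' press is inside when some change of the matching side has it within
#' `[trigger, trigger + cutoff)`); the two percentages sum to 100 exactly.
#'
#' @param matched_rts Numeric vector of matched reaction times (seconds);
#'   at least 2 are required in derived mode.
#' @param mode `"derived"`, `"fixed"` or `"paper_default"`.
#' @param fixed_s Cutoff value for `"fixed"` mode.
#' @param presses,events Optional: the press table and change events used to
#'   compute the inside/outside-window percentages.
#' @return Object of class `cb_cutoff`: `cutoff_s`, `mode`, `n_rts_used`,
#'   `inside_fraction`, `outside_fraction`.
#' @export
#' @examples
#' derive_rt_cutoff(c(1, 2, 3))$cutoff_s # 5
derive_rt_cutoff <- function(matched_rts = numeric(),
                             mode = c("derived", "fixed", "paper_default"),
                             fixed_s = NULL,
                             presses = NULL, events = NULL) {
  mode <- match.arg(mode)
  cutoff <- switch(mode,
    derived = {
      if (length(matched_rts) < 2) {
        abort_estimation(
          "at least 2 matched reaction times are needed to derive a cutoff"
        )
      }
      mean(matched_rts) + 3 * sd(matched_rts)
    },
    fixed = {
      if (is.null(fixed_s) || fixed_s <= 0) {
        abort_config("fixed mode requires a positive fixed_s")
      }
      fixed_s
    },
    paper_default = RT_CUTOFF_PAPER_S
  )
  inside <- NA_real_
  outside <- NA_real_
  if (!is.null(presses) && !is.null(events) && nrow(presses) > 0) {
    ok <- press_inside_window(events, presses, cutoff)
    inside <- 100 * sum(ok) / length(ok)
    outside <- 100 - inside
  }
  structure(
    list(
      cutoff_s = cutoff, mode = mode,
      n_rts_used = length(matched_rts),
      inside_fraction = inside, outside_fraction = outside
    ),
    class = "cb_cutoff"
  )
}

#' @export
print.cb_cutoff <- function(x, ...) {
  cat(sprintf("<cb_cutoff> %.3f s (%s, n = %d)", x$cutoff_s, x$mode,
    x$n_rts_used))
  if (!is.na(x$inside_fraction)) {
    cat(sprintf("; %.1f%% of presses inside / %.1f%% outside the window",
      x$inside_fraction, x$outside_fraction))
  }
  cat("\n")
  invisible(x)
}

# TRUE for each press that falls in [trigger, trigger + cutoff) of some
# change requiring its side
press_inside_window <- function(events, presses, cutoff_s) {
  side_ev <- required_side(events$change_type)
  vapply(seq_len(nrow(presses)), function(i) {
    any(side_ev == presses$side[i] &
      presses$t[i] >= events$trigger_t &
      presses$t[i] < events$trigger_t + cutoff_s)
  }, logical(1))
}

#' Match button presses to change events
#'
#' Attributes each press to at most one change under C1 (matching side),
#' the cutoff window `[trigger, trigger + cutoff_s)`, and C2 (the press
#' precedes the trigger of the next change requiring the same side).
#' Ties break deterministically: the earliest qualifying press wins a
#' change, and the earliest change (in trigger order, behaviour change
#' first at equal triggers) wins a press. Unattributed presses are returned
#' as false alarms; unmatched changes are misses. Every press ends up in
#' exactly one of the two sets.
#'
#' @param events Change events (time-ordered schedule).
#' @param presses Press table (`t`, `side`).
#' @param cutoff_s Positive reaction-time cutoff (seconds).
#' @return List with `outcomes` (one row per change: `change_id`,
#'   `detected`, `rt_s`, `press_t`) and `false_alarms` (`t`, `side`).
#' @export
match_presses <- function(events, presses, cutoff_s) {
  if (cutoff_s <= 0) abort_argument("cutoff_s must be positive")
  ord <- order(events$trigger_t, events$change_type == "property")
  ev <- events[ord, ]
  side_ev <- required_side(ev$change_type)
  n_ev <- nrow(ev)

  # next trigger of a change requiring the same side (Inf when none)
  next_same <- rep(Inf, n_ev)
  for (s in c("left", "right")) {
    idx <- which(side_ev == s)
    if (length(idx) > 1) {
      next_same[idx[-length(idx)]] <- ev$trigger_t[idx[-1]]
    }
  }

  taken <- rep(FALSE, nrow(presses))
  detected <- rep(FALSE, n_ev)
  rt_s <- rep(NA_real_, n_ev)
  press_t <- rep(NA_real_, n_ev)
  for (i in seq_len(n_ev)) {
    cand <- which(!taken &
      presses$side == side_ev[i] &
      presses$t >= ev$trigger_t[i] &
      presses$t < ev$trigger_t[i] + cutoff_s &
      presses$t < next_same[i])
    if (length(cand)) {
      w <- cand[which.min(presses$t[cand])]
      taken[w] <- TRUE
      detected[i] <- TRUE
      rt_s[i] <- presses$t[w] - ev$trigger_t[i]
      press_t[i] <- presses$t[w]
    }
  }
  outcomes <- tibble::tibble(
    change_id = ev$change_id, detected = detected,
    rt_s = rt_s, press_t = press_t
  )
  # restore the caller's event order
  outcomes <- outcomes[match(events$change_id, outcomes$change_id), ]
  list(
    outcomes = outcomes,
    false_alarms = presses[!taken, , drop = FALSE]
  )
}

#' Code the responses of one session
#'
#' Two-stage coding: a preliminary C1 matching with a generous window
#' (default 10 s) supplies the matched reaction times; the cutoff is then
#' obtained per `cutoff_mode` and matching is re-run against it. For
#' cohort-level derivation (RTs pooled across subjects) run the first stage
#' per session yourself and pass a `"fixed"` cutoff; [run_pipeline()] does
#' exactly that.
#'
#' @param events,presses Streams of one session.
#' @param cutoff_mode `"derive"`, `"fixed"` or `"paper_default"`.
#' @param cutoff_s Value for `"fixed"` mode.
#' @param prelim_window_s Window of the first-pass matching (default 10 s).
#' @return List `outcomes`, `false_alarms`, `cutoff` (a `cb_cutoff`).
#' @export
code_responses <- function(events, presses,
                           cutoff_mode = c("derive", "fixed",
                             "paper_default"),
                           cutoff_s = NULL, prelim_window_s = 10) {
  cutoff_mode <- match.arg(cutoff_mode)
  cut <- switch(cutoff_mode,
    derive = {
      prelim <- match_presses(events, presses, prelim_window_s)
      rts <- prelim$outcomes$rt_s[!is.na(prelim$outcomes$rt_s)]
      derive_rt_cutoff(rts, mode = "derived", presses = presses,
        events = events)
    },
    fixed = derive_rt_cutoff(mode = "fixed", fixed_s = cutoff_s,
      presses = presses, events = events),
    paper_default = derive_rt_cutoff(mode = "paper_default",
      presses = presses, events = events)
  )
  m <- match_presses(events, presses, cut$cutoff_s)
  list(outcomes = m$outcomes, false_alarms = m$false_alarms, cutoff = cut)
}

#' Detection-rate table
#'
#' Per-cell detected counts, totals and percentages over any grouping of
#' the outcome table (subsets of participant, change type, complexity, gap
#' and encounter order). Cells with no trials are simply absent.
#'
#' @param outcomes Outcome table carrying `detected` plus the grouping
#'   columns.
#' @param group_by Character vector of grouping column names.
#' @return Tibble with the grouping columns plus `n`, `n_detected`,
#'   `rate_pct`.
#' @export
detection_table <- function(outcomes,
                            group_by = c("change_type", "complexity")) {
  if (nrow(outcomes) == 0) abort_argument("outcomes must be non-empty")
  missing_cols <- setdiff(group_by, names(outcomes))
  if (length(missing_cols)) {
    abort_argument(sprintf("outcomes lack grouping column(s): %s",
      paste(missing_cols, collapse = ", ")))
  }
  outcomes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_detected = sum(.data$detected),
      rate_pct = 100 * sum(.data$detected) / dplyr::n(),
      .groups = "drop"
    )
}
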