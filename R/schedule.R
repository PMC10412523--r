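#' Specification of a change-event schedule
#'
#' Describes the experimental design of one driving session: 12 pairs of
#' changes per complexity level (36 pairs, 72 changes in total), each pair
#' holding one behaviour change followed by one property change separated by
#' one of six time gaps (0, 1, 2, 4, 6 or 8 s), with consecutive pairs at
#' least 10 s apart. The complexity blocks are traversed in the group's
#' order (see [complexity_order()]).
#'
#' @param group Experimental group, `"A"`, `"B"` or `"C"`.
#' @param n_pairs_per_level Pairs of changes per complexity level (default 12).
#'   Must be a multiple of `length(gap_levels_s)` so gap levels can be
#'   balanced within each level.
#' @param gap_levels_s Time gaps (seconds) between the behaviour and property
#'   change of a pair.
#' @param min_interpair_gap_s Minimum time between the property change of one
#'   pair and the behaviour change of the next (default 10 s).
#' @param max_interpair_gap_s Upper bound of the uniform inter-pair spacing
#'   draw (default 60 s, keeping sessions near 20 minutes).
#' @param n_relevant_per_level How many of the behaviour changes per level are
#'   behaviour-relevant (the rest are behaviour-irrelevant; default an even
#'   6/6 split).
#' @param segment_lead_s Quiet time at the start and end of each complexity
#'   segment (default 15 s).
#' @param seed Optional integer driving gap assignment and spacing draws.
#' @return An object of class `cb_schedule_spec`.
#' @seealso [build_schedule()], [validate_schedule()]
#' @export
schedule_spec <- function(group = "A",
                          n_pairs_per_level = 12,
                          gap_levels_s = GAP_LEVELS_S,
                          min_interpair_gap_s = 10,
                          max_interpair_gap_s = 60,
                          n_relevant_per_level = n_pairs_per_level / 2,
                          segment_lead_s = 15,
                          seed = NULL) {
  group <- match.arg(group, c("A", "B", "C"))
  if (n_pairs_per_level < 1 || n_pairs_per_level %% 1 != 0) {
    abort_schedule("n_pairs_per_level must be a positive integer")
  }
  if (length(gap_levels_s) < 1 || anyDuplicated(gap_levels_s)) {
    abort_schedule("gap_levels_s must be distinct")
  }
  if (n_pairs_per_level %% length(gap_levels_s) != 0) {
    abort_schedule("n_pairs_per_level must be a multiple of the number of gap levels")
  }
  if (min_interpair_gap_s <= max(gap_levels_s) ||
      max_interpair_gap_s < min_interpair_gap_s) {
    abort_schedule("inter-pair spacing bounds are infeasible")
  }
  if (n_relevant_per_level < 0 || n_relevant_per_level > n_pairs_per_level) {
    abort_schedule("n_relevant_per_level must lie in [0, n_pairs_per_level]")
  }
  structure(
    list(
      group = group,
      n_pairs_per_level = as.integer(n_pairs_per_level),
      gap_levels_s = sort(gap_levels_s),
      min_interpair_gap_s = min_interpair_gap_s,
      max_interpair_gap_s = max_interpair_gap_s,
      n_relevant_per_level = as.integer(n_relevant_per_level),
      segment_lead_s = segment_lead_s,
      seed = seed
    ),
    class = "cb_schedule_spec"
  )
}

#' Build a change-event schedule
#'
#' Lays out the 72 changes of a session: for each complexity block (in the
#' group's order), 12 pairs are placed along the timeline; within each pair
#' the behaviour change precedes the property change by exactly the pair's
#' gap, gap levels are balanced within every level (each used
#' `n_pairs_per_level / 6` times per level), behaviour changes are split
#' between relevant and irrelevant per the spec, and consecutive pairs are
#' separated by a uniform draw from
#' `[min_interpair_gap_s, max_interpair_gap_s]`.
#'
#' @param spec A [schedule_spec()].
#' @return A tibble of change events (one row per change, time-ordered) with
#'   columns `change_id`, `pair_id`, `change_type`, `complexity`, `trigger_t`,
#'   `aoi_id`, `gap_s`, `encounter_index`, and attributes `segment_bounds`
#'   (a tibble `complexity`, `start_t`, `end_t` partitioning the session) and
#'   `group`.
#' @export
#' @examples
#' ev <- build_schedule(schedule_spec(group = "C", seed = 1))
#' nrow(ev) # 72
build_schedule <- function(spec) {
  if (!inherits(spec, "cb_schedule_spec")) {
    abort_argument("spec must be a cb_schedule_spec")
  }
  with_seed_if(spec$seed, {
    levels_in_order <- complexity_order(spec$group)
    npl <- spec$n_pairs_per_level
    reps <- npl / length(spec$gap_levels_s)

    rows <- vector("list", 3L * npl)
    seg <- vector("list", 3L)
    cursor <- 0
    pair_no <- 0L

    for (k in seq_along(levels_in_order)) {
      lev <- levels_in_order[k]
      seg_start <- cursor
      gaps <- sample(rep(spec$gap_levels_s, reps))
      btype <- sample(rep(
        c("behaviour_relevant", "behaviour_irrelevant"),
        c(spec$n_relevant_per_level, npl - spec$n_relevant_per_level)
      ))
      t_b <- seg_start + spec$segment_lead_s
      for (i in seq_len(npl)) {
        pair_no <- pair_no + 1L
        pid <- sprintf("pair%02d", pair_no)
        t_p <- t_b + gaps[i]
        rows[[pair_no]] <- tibble::tibble(
          change_id = paste0(pid, c("_b", "_p")),
          pair_id = pid,
          change_type = c(btype[i], "property"),
          complexity = lev,
          trigger_t = c(t_b, t_p),
          aoi_id = paste0("aoi_", pid, c("_b", "_p")),
          gap_s = gaps[i]
        )
        t_b <- t_p +
          runif(1, spec$min_interpair_gap_s, spec$max_interpair_gap_s)
      }
      seg_end <- rows[[pair_no]]$trigger_t[2] + spec$segment_lead_s
      seg[[k]] <- tibble::tibble(
        complexity = lev, start_t = seg_start, end_t = seg_end
      )
      cursor <- seg_end
    }

    events <- dplyr::bind_rows(rows)
    events$encounter_index <- seq_len(nrow(events))
    attr(events, "segment_bounds") <- dplyr::bind_rows(seg)
    attr(events, "group") <- spec$group
    class(events) <- c("cb_schedule", class(events))
    events
  })
}

#' Validate a change-event schedule
#'
#' Checks the design invariants of a schedule and returns the violations
#' found (an empty tibble when the schedule is valid): total/per-type counts,
#' pair composition and ordering, gap-level balance, inter-pair spacing, and
#' the complexity-block order for the group.
#'
#' @param events A schedule as returned by [build_schedule()] (or any tibble
#'   with the same columns).
#' @param spec The [schedule_spec()] the schedule should satisfy; defaults to
#'   a spec for the schedule's own group attribute.
#' @return A tibble with columns `rule`, `ids`, `message`; zero rows when
#'   every invariant holds.
#' @export
validate_schedule <- function(events,
                              spec = schedule_spec(
                                group = attr(events, "group") %||% "A"
                              )) {
  if (nrow(events) == 0) abort_argument("events must be non-empty")
  v <- list()
  note <- function(rule, ids, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      rule = rule, ids = paste(ids, collapse = ","), message = message
    )
  }

  n_expected <- 2L * 3L * spec$n_pairs_per_level
  if (nrow(events) != n_expected) {
    note("n_changes", character(), sprintf(
      "expected %d changes, found %d", n_expected, nrow(events)
    ))
  }
  n_beh <- sum(events$change_type %in%
    c("behaviour_relevant", "behaviour_irrelevant"))
  n_prop <- sum(events$change_type == "property")
  if (n_beh != n_prop) {
    note("type_balance", character(), sprintf(
      "behaviour (%d) and property (%d) counts differ", n_beh, n_prop
    ))
  }

  by_pair <- split(events, events$pair_id)
  for (pid in names(by_pair)) {
    p <- by_pair[[pid]]
    if (nrow(p) != 2 || sum(p$change_type == "property") != 1) {
      note("pair_composition", pid,
        "a pair must hold exactly one behaviour and one property change")
      next
    }
    b <- p[p$change_type != "property", ]
    pr <- p[p$change_type == "property", ]
    if (b$trigger_t > pr$trigger_t + 1e-9) {
      note("pair_order", pid, "behaviour change must precede property change")
    }
    if (abs((pr$trigger_t - b$trigger_t) - p$gap_s[1]) > 1e-6) {
      note("pair_gap", pid, sprintf(
        "trigger difference %.3f s does not equal gap %.3f s",
        pr$trigger_t - b$trigger_t, p$gap_s[1]
      ))
    }
    if (!p$gap_s[1] %in% spec$gap_levels_s) {
      note("gap_level", pid, sprintf("gap %.3f s is not a design level",
        p$gap_s[1]))
    }
  }

  # gap balance across pairs (one gap value per pair)
  pair_gaps <- vapply(by_pair, function(p) p$gap_s[1], numeric(1))
  want <- length(pair_gaps) / length(spec$gap_levels_s)
  counts <- table(factor(pair_gaps, levels = spec$gap_levels_s))
  off <- counts != want
  if (any(off)) {
    note("gap_balance", names(counts)[off], sprintf(
      "each gap level must be used %d times; counts: %s",
      want, paste(counts, collapse = "/")
    ))
  }

  # pairs per complexity level
  pair_lev <- vapply(by_pair, function(p) p$complexity[1], character(1))
  lev_counts <- table(factor(pair_lev, levels = COMPLEXITY_LEVELS))
  off <- lev_counts != spec$n_pairs_per_level
  if (any(off)) {
    note("pairs_per_level", names(lev_counts)[off], sprintf(
      "each level must hold %d pairs", spec$n_pairs_per_level
    ))
  }

  # inter-pair spacing: next behaviour trigger - previous property trigger
  pr <- events[events$change_type == "property", ]
  bh <- events[events$change_type != "property", ]
  o <- order(bh$trigger_t)
  bh <- bh[o, ]
  pr <- pr[match(bh$pair_id, pr$pair_id), ]
  if (nrow(bh) > 1) {
    spacing <- bh$trigger_t[-1] - pr$trigger_t[-nrow(pr)]
    bad <- which(spacing < spec$min_interpair_gap_s - 1e-9)
    if (length(bad)) {
      note("min_interpair_gap", bh$pair_id[bad + 1], sprintf(
        "minimum inter-pair spacing %.2f s is below %.2f s",
        min(spacing), spec$min_interpair_gap_s
      ))
    }
  }

  # complexity block order along the timeline
  lev_seq <- rle(events$complexity[order(events$trigger_t,
    events$change_type == "property")])$values
  if (!identical(lev_seq, complexity_order(spec$group))) {
    note("group_order", character(), sprintf(
      "complexity blocks run %s but group %s requires %s",
      paste(lev_seq, collapse = "-"), spec$group,
      paste(complexity_order(spec$group), collapse = "-")
    ))
  }

  if (length(v) == 0) {
    tibble::tibble(rule = character(), ids = character(),
      message = character())
  } else {
    dplyr::bind_rows(v)
  }
}
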