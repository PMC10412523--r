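# Synthetic multimodal session generator. The generator writes the
# statistical structure the analysis assumes into the streams: Bernoulli
# detections per (change type x complexity) cell, a truncated-lognormal RT
# law, planned AOI dwells in the event-aligned windows (anticipatory onsets
# for behaviour-relevant changes, lingering for detected property changes),
# a fixation/saccade renewal process at 120 Hz, and per-complexity driving
# profiles.

GENERATOR_VERSION <- "drivecb-sim-1"

#' Simulate one participant session
#'
#' Generates a fully validated [session_log()] for a given change-event
#' schedule. Gaze is produced as an alternating fixation/saccade renewal
#' process at 120 Hz from a static head position: baseline fixations aim at
#' a forward road region with small angular jitter, and for each change an
#' AOI dwell of at least 100 ms is planted in the pre/post 4 s window with
#' the configured probability. Detections are drawn per cell (with the
#' learning increment applied to property changes by encounter order) and
#' produce a press at `trigger + RT` on the correct side except with
#' probability `wrong_button_p`; false alarms arrive as a homogeneous
#' process. Everything is deterministic given `seed`.
#'
#' @param params A [driver_params()].
#' @param schedule A schedule from [build_schedule()].
#' @param seed Integer seed (required).
#' @param participant_id,group Identity of the synthetic participant; the
#'   group defaults to the schedule's group.
#' @param include_gaze,include_driving Generate the gaze / driving streams
#'   (default TRUE). Disabling them yields a presses-plus-events session,
#'   useful for large response-coding simulations.
#' @return A `cb_session`.
#' @export
simulate_session <- function(params, schedule, seed,
                             participant_id = "p001",
                             group = attr(schedule, "group") %||% "A",
                             include_gaze = TRUE,
                             include_driving = TRUE) {
  if (!inherits(params, "cb_driver_params")) {
    abort_argument("params must be a cb_driver_params")
  }
  if (missing(seed) || is.null(seed)) abort_argument("seed is required")
  events <- schedule
  segment_bounds <- attr(schedule, "segment_bounds")
  if (is.null(segment_bounds)) {
    abort_generation("schedule carries no segment_bounds attribute")
  }
  t_end <- max(segment_bounds$end_t)

  with_seed_if(seed, {
    aois <- build_aois(events)
    resp <- draw_responses(params, events, t_end)
    gaze <- if (include_gaze) {
      synth_gaze(params, events, aois, segment_bounds, resp$detected, t_end)
    } else {
      empty_gaze()
    }
    driving <- if (include_driving) {
      synth_driving(params, segment_bounds)
    } else {
      empty_driving()
    }
    session_log(
      participant_id = participant_id, group = group,
      gaze = gaze, driving = driving, presses = resp$presses,
      events = events, aois = aois, segment_bounds = segment_bounds,
      meta = list(
        seed = seed, generator = GENERATOR_VERSION,
        speed_limit_kmh = SPEED_LIMIT_KMH
      )
    )
  })
}

#' Simulate a cohort of participants
#'
#' Groups are cycled A, B, C; all participants of a group share the group's
#' schedule (changes are triggered at fixed points along the route), while
#' behaviour is drawn from independent per-participant RNG substreams.
#'
#' @inheritParams simulate_session
#' @param n Number of participants (>= 1).
#' @param seed Master seed; schedule and participant substream seeds are
#'   derived from it.
#' @return Named list of `cb_session` objects.
#' @export
#' @examples
#' cohort <- simulate_cohort(3, default_params(), seed = 7,
#'   include_gaze = FALSE, include_driving = FALSE)
#' vapply(cohort, function(s) s$group, character(1))
simulate_cohort <- function(n, params = default_params(), seed = 1,
                            include_gaze = TRUE, include_driving = TRUE) {
  if (n < 1) abort_argument("n must be at least 1")
  seeds <- withr::with_seed(seed, {
    list(
      schedule = sample.int(.Machine$integer.max, 3),
      participant = sample.int(.Machine$integer.max, n)
    )
  })
  groups <- c("A", "B", "C")
  schedules <- lapply(seq_along(groups), function(i) {
    build_schedule(schedule_spec(group = groups[i], seed = seeds$schedule[i]))
  })
  names(schedules) <- groups
  sessions <- lapply(seq_len(n), function(i) {
    g <- groups[(i - 1L) %% 3L + 1L]
    simulate_session(
      params, schedules[[g]],
      seed = seeds$participant[i],
      participant_id = sprintf("p%03d", i), group = g,
      include_gaze = include_gaze, include_driving = include_driving
    )
  })
  names(sessions) <- vapply(sessions, `[[`, character(1), "participant_id")
  sessions
}

# ---- internals ------------------------------------------------------------

# AOI geometry: targets sit 8-15 m away at 15-35 degrees azimuth; the two
# changes of a pair sit on opposite sides of the road, so their AOIs (about
# 4-7 degrees angular radius at 1 m physical radius) never overlap, and the
# forward road region stays clear of both.
build_aois <- function(events) {
  aois <- vector("list", nrow(events))
  side_of_pair <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(events))) {
    pid <- events$pair_id[i]
    if (is.null(side_of_pair[[pid]])) {
      side_of_pair[[pid]] <- sample(c(-1, 1), 1)
    }
    s <- side_of_pair[[pid]]
    is_prop <- events$change_type[i] == "property"
    az <- deg2rad((if (is_prop) -s else s) * runif(1, 15, 35))
    dist <- runif(1, 8, 15)
    center <- dist * c(cos(az), sin(az), 0)
    kind <- if (is_prop) "object" else "agent"
    trig <- events$trigger_t[i]
    tt <- seq(trig - 5, trig + 5, by = 0.5)
    vel <- if (kind == "agent") {
      0.25 * sample(c(-1, 1), 1) * c(-sin(az), cos(az), 0)
    } else {
      c(0, 0, 0)
    }
    aois[[i]] <- list(
      aoi_id = events$aoi_id[i], kind = kind, radius = 1,
      track = tibble::tibble(
        t = tt,
        x = center[1] + vel[1] * (tt - trig),
        y = center[2] + vel[2] * (tt - trig),
        z = center[3] + vel[3] * (tt - trig)
      )
    )
  }
  names(aois) <- events$aoi_id
  aois
}

draw_responses <- function(params, events, t_end) {
  n <- nrow(events)
  p <- params$p_detect[cbind(events$change_type, events$complexity)]
  is_prop <- events$change_type == "property"
  p[is_prop] <- clamp(
    p[is_prop] + params$learning_slope * (events$encounter_index[is_prop] - 1),
    0, 1
  )
  detected <- runif(n) < p
  rt <- rlnorm_trunc(n, params$rt_meanlog, params$rt_sdlog, params$rt_max_s)
  side <- required_side(events$change_type)
  flip <- runif(n) < params$wrong_button_p
  side[flip] <- ifelse(side[flip] == "left", "right", "left")
  presses <- tibble::tibble(
    t = events$trigger_t[detected] + rt[detected],
    side = side[detected]
  )
  n_fa <- rpois(1, params$false_alarm_rate_per_min * t_end / 60)
  if (n_fa > 0) {
    presses <- dplyr::bind_rows(presses, tibble::tibble(
      t = runif(n_fa, 0, t_end),
      side = sample(c("left", "right"), n_fa, replace = TRUE)
    ))
  }
  list(presses = presses[order(presses$t), ], detected = detected)
}

# plant AOI dwell intervals in the event-aligned windows, avoiding overlap
# with already-planted intervals (rejection sampling inside the window)
plan_aoi_fixations <- function(params, events, detected) {
  placed <- matrix(numeric(0), ncol = 2) # start, end
  rows <- list()
  overlaps <- function(a, b) {
    nrow(placed) > 0 && any(a < placed[, 2] + 0.05 & b > placed[, 1] - 0.05)
  }
  place <- function(lo, hi, dur, preferred = NA) {
    # interval of length dur inside [lo, hi]; preferred onset first
    if (hi - lo < dur) return(NULL)
    for (try in 1:40) {
      a <- if (!is.na(preferred) && try <= 10) {
        clamp(preferred + (try - 1) * 0.1 * sample(c(-1, 1), 1), lo, hi - dur)
      } else {
        runif(1, lo, hi - dur)
      }
      if (!overlaps(a, a + dur)) {
        placed <<- rbind(placed, c(a, a + dur))
        return(c(a, a + dur))
      }
    }
    NULL
  }
  for (i in seq_len(nrow(events))) {
    type <- events$change_type[i]
    trig <- events$trigger_t[i]
    if (runif(1) < params$p_gaze_pre[[type]]) {
      dur <- runif(1, 0.18, 0.35)
      pref <- if (type == "behaviour_relevant") {
        trig - params$anticipatory_lead_s + rnorm(1, 0, 0.15)
      } else {
        NA
      }
      iv <- place(trig - 3.9, trig - 0.05, dur, pref)
      if (!is.null(iv)) {
        rows[[length(rows) + 1]] <- c(iv, i)
      }
    }
    if (runif(1) < params$p_gaze_post[[type]]) {
      dur <- runif(1, 0.18, 0.35)
      iv <- place(trig + 0.05, trig + 3.9, dur)
      if (!is.null(iv)) {
        rows[[length(rows) + 1]] <- c(iv, i)
      }
    }
    if (type == "property" && detected[i] && params$linger_extra_s > 0) {
      dur <- max(0.15, params$linger_extra_s)
      iv <- place(trig + 2.7, trig + 3.9, dur, trig + 2.9)
      if (!is.null(iv)) {
        rows[[length(rows) + 1]] <- c(iv, i)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
      event_row = integer()))
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(start = m[, 1], end = m[, 2],
    event_row = as.integer(m[, 3]))
  out[order(out$start), ]
}

# baseline renewal fixations filling [a, b] at roughly `rate` fixations/s
fill_baseline <- function(a, b, rate, params) {
  if (b - a < 0.16) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  n_est <- ceiling((b - a) * rate) + 8
  durs <- rlnorm_trunc2(n_est, params$fix_dur_meanlog, params$fix_dur_sdlog,
    0.1, 0.5)
  extra_mean <- max(0.005, 1 / rate - 0.28)
  gaps <- 0.03 + rexp(n_est, 1 / extra_mean)
  ends <- a + cumsum(gaps + durs)
  starts <- ends - durs
  keep <- ends <= b - 0.02
  tibble::tibble(start = starts[keep], end = ends[keep])
}

synth_gaze <- function(params, events, aois, segment_bounds, detected,
                       t_end) {
  aoi_fix <- plan_aoi_fixations(params, events, detected)

  # fill the gaps between planted AOI fixations with road fixations, at the
  # complexity-specific baseline rate of the segment the gap starts in
  seg_rate <- params$fixation_rate_hz[segment_bounds$complexity]
  gap_edges <- c(0, as.numeric(t(cbind(aoi_fix$start, aoi_fix$end))), t_end)
  base <- list()
  for (k in seq_len(length(gap_edges) / 2)) {
    a <- gap_edges[2 * k - 1]
    b <- gap_edges[2 * k]
    rate <- seg_rate[segment_index_at(segment_bounds, min(a, t_end - 1e-6))]
    base[[k]] <- fill_baseline(a, b, rate, params)
  }
  base <- dplyr::bind_rows(base)

  # targets: AOI fixations aim at the AOI centre at the fixation midpoint;
  # road fixations aim far ahead, alternating sides so consecutive targets
  # stay several degrees apart
  plan <- dplyr::bind_rows(
    tibble::tibble(start = aoi_fix$start, end = aoi_fix$end,
      event_row = aoi_fix$event_row),
    tibble::tibble(start = base$start, end = base$end,
      event_row = NA_integer_)
  )
  plan <- plan[order(plan$start), ]
  k <- nrow(plan)
  if (k == 0) abort_generation("gaze plan is empty")
  targets <- matrix(0, k, 3)
  road <- which(is.na(plan$event_row))
  if (length(road)) {
    sgn <- rep_len(c(-1, 1), length(road))
    az <- deg2rad(sgn * (1.5 + abs(rnorm(length(road), 0, 1.2))))
    el <- deg2rad(rnorm(length(road), 0, 0.7))
    targets[road, ] <- 30 * cbind(cos(az) * cos(el), sin(az) * cos(el),
      sin(el))
  }
  for (j in which(!is.na(plan$event_row))) {
    a <- aois[[events$aoi_id[plan$event_row[j]]]]
    targets[j, ] <- interp_track(a$track, (plan$start[j] + plan$end[j]) / 2)
  }
  dirs <- unit_rows(targets)

  # synthesise the 120 Hz sample stream
  t <- seq(0, t_end, by = 1 / GAZE_HZ)
  n <- length(t)
  idx <- findInterval(t, plan$start)
  idx0 <- pmax(idx, 1L)
  in_fix <- idx >= 1L & t < plan$end[idx0]
  g <- dirs[idx0, , drop = FALSE]
  sac <- which(!in_fix & idx >= 1L & idx < k)
  if (length(sac)) {
    ka <- idx[sac]
    A <- dirs[ka, , drop = FALSE]
    B <- dirs[ka + 1L, , drop = FALSE]
    f <- (t[sac] - plan$end[ka]) / (plan$start[ka + 1L] - plan$end[ka])
    om <- acos(clamp(rowSums(A * B), -1, 1))
    sm <- pmax(sin(om), 1e-9)
    # fall back to linear blending when the endpoints (nearly) coincide
    near <- om < 1e-6
    w1 <- ifelse(near, 1 - f, sin((1 - f) * om) / sm)
    w2 <- ifelse(near, f, sin(f * om) / sm)
    g[sac, ] <- w1 * A + w2 * B
  }
  jit <- which(in_fix)
  g[jit, ] <- g[jit, ] + matrix(rnorm(3 * length(jit), 0, params$gaze_jitter),
    ncol = 3)
  g <- unit_rows(g)

  tibble::tibble(
    t = t, gx = g[, 1], gy = g[, 2], gz = g[, 3],
    hx = 0, hy = 0, hz = 0, valid = TRUE
  )
}

synth_driving <- function(params, segment_bounds) {
  out <- list()
  for (i in seq_len(nrow(segment_bounds))) {
    a <- segment_bounds$start_t[i]
    b <- segment_bounds$end_t[i]
    lev <- segment_bounds$complexity[i]
    t <- seq(a, b - 1e-9, by = 0.1)
    n <- length(t)
    noise <- as.numeric(filter(rnorm(n, 0, 1.8), rep(1 / 6, 6),
      sides = 1))
    noise[is.na(noise)] <- 0
    speed <- clamp(params$speed_kmh[[lev]] + noise, 3, SPEED_LIMIT_KMH)
    brake <- rep(FALSE, n)
    n_ev <- rpois(1, params$brake_rate_per_min[[lev]] * (b - a) / 60)
    if (n_ev > 0) {
      onsets <- runif(n_ev, a, b - 0.5)
      for (o in onsets) brake[t >= o & t < o + 0.4] <- TRUE
    }
    out[[i]] <- tibble::tibble(t = t, speed_kmh = speed, brake = brake)
  }
  dplyr::bind_rows(out)
}
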