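test_that("gaze categories follow the dwell threshold", {
  expect_identical(gaze_category(150, 150), "both")
  expect_identical(gaze_category(150, 50), "before_only")
  expect_identical(gaze_category(40, 120), "after_only")
  expect_identical(gaze_category(0, 0), "none")
  expect_identical(
    gaze_category(c(150, 150, 40, 0), c(150, 50, 120, 0)),
    c("both", "before_only", "after_only", "none")
  )
  expect_error(gaze_category(-1, 50), class = "cb_argument_error")
})

test_that("LBFTS requires a miss with both-window gaze", {
  cfg <- lbfts_config()
  expect_true(classify_lbfts(FALSE, 150, 150, cfg))
  expect_false(classify_lbfts(TRUE, 150, 150, cfg))
  expect_false(classify_lbfts(FALSE, 0, 150, cfg))
  expect_false(classify_lbfts(FALSE, 150, 99, cfg))
  expect_error(lbfts_config(pre_window_s = 0), class = "cb_argument_error")
  expect_error(lbfts_config(min_dwell_ms = 5000),
    class = "cb_argument_error")
})

test_that("gaze categories partition trials and LBFTS sits inside misses", {
  oc <- toy_outcomes()
  counts <- table(factor(oc$gaze_category,
    levels = c("before_only", "after_only", "both", "none")))
  expect_equal(sum(counts), nrow(oc))
  expect_true(all(oc$gaze_category[oc$lbfts] == "both"))
  expect_true(all(!oc$detected[oc$lbfts]))

  tab <- lbfts_table(oc)
  expect_equal(sum(tab$n_all), nrow(oc))
  expect_true(all(tab$n_lbfts <= tab$n_gazers))
  # empty denominators report NA, never 0/0
  expect_true(all(is.na(tab$rate_gazers_pct[tab$n_gazers == 0])))
})

test_that("LBFTS rates hit the forced limits of the generator", {
  all_gaze <- c(behaviour_relevant = 1, behaviour_irrelevant = 1,
    property = 1)
  ev <- build_schedule(mini_spec(seed = 31))

  blind <- driver_params(p_detect = p_detect_matrix(0),
    false_alarm_rate_per_min = 0, learning_slope = 0,
    p_gaze_pre = all_gaze, p_gaze_post = all_gaze)
  s <- simulate_session(blind, ev, seed = 32)
  fx <- detect_fixations(s$gaze)
  gz <- drivecb:::process_session_gaze(s, fx, lbfts_config())
  oc <- dplyr::bind_cols(s$events, gz$per_event)
  oc$detected <- FALSE
  oc$lbfts <- classify_lbfts(oc$detected, oc$dwell_pre_ms,
    oc$dwell_post_ms)
  expect_true(all(lbfts_table(oc)$rate_gazers_pct == 100))
  expect_true(all(lbfts_table(oc)$rate_all_pct == 100))

  oc$detected <- TRUE
  oc$lbfts <- classify_lbfts(oc$detected, oc$dwell_pre_ms,
    oc$dwell_post_ms)
  expect_true(all(lbfts_table(oc)$rate_gazers_pct == 0))
})

test_that("shrinking the pre-window never adds both-window gazers", {
  ev <- build_schedule(mini_spec(seed = 41))
  s <- simulate_session(default_params(), ev, seed = 42)
  fx <- detect_fixations(s$gaze)
  g4 <- drivecb:::process_session_gaze(s, fx, lbfts_config())$per_event
  g2 <- drivecb:::process_session_gaze(s, fx,
    lbfts_config(pre_window_s = 2))$per_event
  expect_lte(sum(g2$gaze_category == "both"),
    sum(g4$gaze_category == "both"))
  expect_true(all(g2$dwell_pre_ms <= g4$dwell_pre_ms + 1e-9))
})

test_that("rate-of-change slopes are adjacent-level differences", {
  flat <- roc_slopes(c(low = 60, medium = 60, high = 60))
  expect_equal(unlist(flat), c(slope_low_medium = 0,
    slope_medium_high = 0, mean_slope = 0))

  r <- roc_slopes(c(low = 60, medium = 56.1, high = 47.08))
  expect_equal(r$slope_low_medium, -3.9)
  expect_equal(r$slope_medium_high, -9.02)
  expect_equal(r$mean_slope, -6.46)

  # additivity: the two slopes always telescope to high - low
  withr::with_seed(13, {
    for (i in 1:20) {
      v <- runif(3, 0, 100)
      s <- roc_slopes(c(low = v[1], medium = v[2], high = v[3]))
      expect_equal(s$slope_low_medium + s$slope_medium_high, v[3] - v[1])
    }
  })
  expect_error(roc_slopes(c(low = 60, high = 47)),
    class = "cb_argument_error")
})

test_that("driving metrics count brake rising edges and weight speed by time", {
  sb <- tibble::tibble(complexity = "low", start_t = 0, end_t = 7)
  drv <- tibble::tibble(
    t = 0:6,
    speed_kmh = 26,
    brake = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  )
  m <- driving_metrics(drv, sb)
  expect_equal(m$brake_hits, 2L)
  expect_equal(m$avg_speed_kmh, 26)
  expect_equal(m$completion_min, 7 / 60)

  # time weighting: 10 km/h held for 8 s, 30 km/h for 2 s
  drv2 <- tibble::tibble(t = c(0, 8), speed_kmh = c(10, 30),
    brake = FALSE)
  sb2 <- tibble::tibble(complexity = "low", start_t = 0, end_t = 10)
  expect_equal(driving_metrics(drv2, sb2)$avg_speed_kmh, 14)

  # empty segment: metrics absent, not zero
  sb3 <- tibble::tibble(complexity = c("low", "high"),
    start_t = c(0, 10), end_t = c(10, 20))
  m3 <- driving_metrics(drv2, sb3)
  expect_true(is.na(m3$avg_speed_kmh[2]))
})

test_that("the temporal proximity table always carries the six gap levels", {
  oc <- toy_outcomes()
  tab <- temporal_proximity_table(oc)
  expect_equal(tab$gap_s, c(0, 1, 2, 4, 6, 8))
  expect_equal(nrow(tab), 6)
  expect_true(all(is.na(tab$rate_pct[tab$n == 0])))

  oc$detected <- TRUE
  tab <- temporal_proximity_table(oc)
  expect_true(all(tab$rate_pct[tab$n > 0] == 100))

  bad <- oc
  bad$gap_s[3] <- 3
  expect_error(temporal_proximity_table(bad),
    class = "cb_validation_error")
})

test_that("learning comparison contrasts the first and third segment", {
  cohort <- simulate_cohort(3, perfect_params(), seed = 6,
    include_gaze = FALSE, include_driving = FALSE)
  oc <- dplyr::bind_rows(lapply(cohort, function(s) {
    m <- match_presses(s$events, s$presses, 4.1)
    dplyr::bind_cols(
      tibble::tibble(participant_id = s$participant_id),
      s$events[, c("change_type", "encounter_index")],
      m$outcomes["detected"]
    )
  }))
  le <- learning_effect(oc)
  expect_equal(le$rate_pct_first, le$rate_pct_last)
  expect_true(all(le$rate_pct_first == 100))
  per <- attr(le, "per_participant")
  expect_true(all(c("first", "last") %in% per$session_half))

  expect_error(learning_effect(oc[oc$encounter_index <= 48, ]),
    class = "cb_validation_error")
})
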