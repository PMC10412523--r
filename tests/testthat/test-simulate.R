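test_that("default parameters are valid and monotone in complexity", {
  p <- default_params()
  expect_s3_class(p, "cb_driver_params")
  expect_true(all(p$p_detect >= 0 & p$p_detect <= 1))
  # detection probability weakly decreases with complexity for every type
  expect_true(all(apply(p$p_detect, 1, function(r) all(diff(r) <= 0))))
  expect_error(driver_params(wrong_button_p = 1.5),
    class = "cb_argument_error")
  expect_error(driver_params(p_detect = matrix(0.5, 2, 3)),
    class = "cb_argument_error")
})

test_that("degenerate parameter limits force the exact press pattern", {
  ev <- build_schedule(mini_spec(seed = 51))

  # perfect detection, degenerate RT at 1 s: one correct-side press at
  # trigger + 1 for every change
  s <- simulate_session(perfect_params(), ev, seed = 52,
    include_gaze = FALSE, include_driving = FALSE)
  expect_equal(nrow(s$presses), nrow(ev))
  expect_equal(sort(s$presses$t), sort(ev$trigger_t + 1))
  m <- match_presses(ev, s$presses, 4.1)
  expect_true(all(m$outcomes$detected))
  expect_equal(m$outcomes$rt_s, rep(1, nrow(ev)))

  # blind driver with no false alarms: zero presses
  blind <- driver_params(p_detect = p_detect_matrix(0),
    false_alarm_rate_per_min = 0, learning_slope = 0)
  s0 <- simulate_session(blind, ev, seed = 53, include_gaze = FALSE,
    include_driving = FALSE)
  expect_equal(nrow(s0$presses), 0)
})

test_that("sessions are deterministic given the seed", {
  ev <- build_schedule(mini_spec(seed = 61))
  a <- simulate_session(default_params(), ev, seed = 62)
  b <- simulate_session(default_params(), ev, seed = 62)
  expect_equal(as.data.frame(a$gaze), as.data.frame(b$gaze))
  expect_equal(as.data.frame(a$presses), as.data.frame(b$presses))
  expect_equal(as.data.frame(a$driving), as.data.frame(b$driving))
  c2 <- simulate_session(default_params(), ev, seed = 63)
  expect_false(identical(a$presses, c2$presses))
  expect_error(simulate_session(default_params(), ev),
    class = "cb_argument_error")
})

test_that("cohorts cycle the three groups with independent substreams", {
  cohort <- simulate_cohort(4, default_params(), seed = 8,
    include_gaze = FALSE, include_driving = FALSE)
  expect_equal(vapply(cohort, `[[`, character(1), "group"),
    c(p001 = "A", p002 = "B", p003 = "C", p004 = "A"))
  # same group shares the schedule, participants differ in behaviour
  expect_equal(cohort$p001$events$trigger_t, cohort$p004$events$trigger_t)
  expect_false(identical(cohort$p001$presses, cohort$p004$presses))
  expect_error(simulate_cohort(0), class = "cb_argument_error")
})

test_that("the gaze stream satisfies its sampling invariants", {
  ev <- build_schedule(mini_spec(seed = 71))
  s <- simulate_session(default_params(), ev, seed = 72)
  g <- s$gaze
  expect_true(all(diff(g$t) > 0))
  dt <- median(diff(g$t))
  expect_lt(abs(dt - 1 / 120) / (1 / 120), 0.2)
  nrm <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  expect_true(all(abs(nrm - 1) < 1e-6))
})

test_that("realised RTs put mean + 3 SD near the 4 s window", {
  p <- default_params()
  withr::with_seed(81, {
    rts <- drivecb:::rlnorm_trunc(20000, p$rt_meanlog, p$rt_sdlog,
      p$rt_max_s)
  })
  cut <- mean(rts) + 3 * sd(rts)
  expect_gt(cut, 3)
  expect_lt(cut, 5)
})

test_that("a default cohort lands in the plausible detection band", {
  cohort <- simulate_cohort(30, default_params(), seed = 91,
    include_gaze = FALSE, include_driving = FALSE)
  oc <- dplyr::bind_rows(lapply(cohort, function(s) {
    code_responses(s$events, s$presses, "paper_default")$outcomes
  }))
  rate <- 100 * mean(oc$detected)
  expect_gt(rate, 45)
  expect_lt(rate, 65)
})

test_that("raising a cell's detection probability raises its measured rate", {
  base <- p_detect_matrix(0.4)
  up <- base
  up["property", "medium"] <- 0.6
  rate_for <- function(pd) {
    prm <- driver_params(p_detect = pd, wrong_button_p = 0,
      false_alarm_rate_per_min = 0, learning_slope = 0)
    cohort <- simulate_cohort(12, prm, seed = 92, include_gaze = FALSE,
      include_driving = FALSE)
    oc <- dplyr::bind_rows(lapply(cohort, function(s) {
      m <- match_presses(s$events, s$presses, 10)
      dplyr::bind_cols(s$events[, c("change_type", "complexity")],
        m$outcomes["detected"])
    }))
    tab <- detection_table(oc)
    tab$rate_pct[tab$change_type == "property" &
      tab$complexity == "medium"]
  }
  expect_gt(rate_for(up), rate_for(base))
})

test_that("planted gaze matches the LBFTS closure identity", {
  # with uniform p_detect and p_gaze, the expected LBFTS fraction over all
  # changes is p_pre * p_post * (1 - p_detect); check within 3 SE
  p_pre <- 0.8
  p_post <- 0.7
  p_det <- 0.5
  prm <- driver_params(
    p_detect = p_detect_matrix(p_det), wrong_button_p = 0,
    false_alarm_rate_per_min = 0, learning_slope = 0,
    p_gaze_pre = c(behaviour_relevant = p_pre,
      behaviour_irrelevant = p_pre, property = p_pre),
    p_gaze_post = c(behaviour_relevant = p_post,
      behaviour_irrelevant = p_post, property = p_post)
  )
  cohort <- simulate_cohort(4, prm, seed = 93, include_driving = FALSE)
  oc <- dplyr::bind_rows(lapply(cohort, function(s) {
    fx <- detect_fixations(s$gaze)
    gz <- drivecb:::process_session_gaze(s, fx, lbfts_config())
    m <- match_presses(s$events, s$presses, 10)
    dplyr::bind_cols(gz$per_event, m$outcomes["detected"])
  }))
  oc$lbfts <- classify_lbfts(oc$detected, oc$dwell_pre_ms,
    oc$dwell_post_ms)
  frac <- mean(oc$lbfts)
  expected <- p_pre * p_post * (1 - p_det)
  se <- sqrt(expected * (1 - expected) / nrow(oc))
  expect_lt(abs(frac - expected), 3 * se + 0.02)
})
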