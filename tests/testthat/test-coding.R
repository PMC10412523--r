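test_that("the RT cutoff is mean + 3 sample SD", {
  expect_equal(derive_rt_cutoff(c(1, 1, 1))$cutoff_s, 1)
  expect_equal(derive_rt_cutoff(c(1, 2, 3))$cutoff_s, 5) # mean 2, sd 1
  expect_equal(derive_rt_cutoff(mode = "paper_default")$cutoff_s, 4.1)
  expect_equal(derive_rt_cutoff(mode = "fixed", fixed_s = 2.5)$cutoff_s,
    2.5)
  expect_error(derive_rt_cutoff(1), class = "cb_estimation_error")
  expect_error(derive_rt_cutoff(mode = "fixed"),
    class = "cb_config_error")
})

test_that("the derived cutoff scales linearly with the RTs", {
  withr::with_seed(7, {
    rts <- rlnorm(40, -0.1, 0.6)
    base <- derive_rt_cutoff(rts)$cutoff_s
    for (k in c(0.5, 2, 3.7)) {
      expect_equal(derive_rt_cutoff(k * rts)$cutoff_s, k * base,
        tolerance = 1e-12)
    }
  })
})

test_that("inside and outside press fractions are exact complements", {
  ev <- tibble::tibble(
    change_id = c("a", "b"), pair_id = c("p1", "p1"),
    change_type = c("behaviour_relevant", "property"),
    complexity = "low", trigger_t = c(10, 12), aoi_id = c("x", "y"),
    gap_s = 2, encounter_index = 1:2
  )
  pr <- tibble::tibble(
    t = c(10.5, 12.4, 30, 40.21),
    side = c("right", "left", "right", "left")
  )
  cut <- derive_rt_cutoff(c(0.5, 0.4, 0.6), presses = pr, events = ev)
  expect_equal(cut$inside_fraction + cut$outside_fraction, 100)
  expect_equal(cut$inside_fraction, 50) # the two late presses are outside
})

test_that("presses are matched under C1, C2 and the cutoff window", {
  ev1 <- tibble::tibble(
    change_id = "c1", change_type = "behaviour_relevant", trigger_t = 10
  )
  # textbook detection: right press 1 s after a behaviour change
  m <- match_presses(ev1, tibble::tibble(t = 11, side = "right"), 4.1)
  expect_true(m$outcomes$detected)
  expect_equal(m$outcomes$rt_s, 1)
  expect_equal(nrow(m$false_alarms), 0)

  # same press too late: miss plus one false alarm
  m <- match_presses(ev1, tibble::tibble(t = 15, side = "right"), 4.1)
  expect_false(m$outcomes$detected)
  expect_equal(nrow(m$false_alarms), 1)

  # wrong side (no property change pending): miss plus false alarm
  m <- match_presses(ev1, tibble::tibble(t = 11, side = "left"), 4.1)
  expect_false(m$outcomes$detected)
  expect_equal(nrow(m$false_alarms), 1)

  # a press at exactly trigger + cutoff is outside (half-open window)
  m <- match_presses(ev1, tibble::tibble(t = 14.1, side = "right"), 4.1)
  expect_false(m$outcomes$detected)
})

test_that("0 s-gap pairs are disambiguated by button side", {
  ev <- tibble::tibble(
    change_id = c("b1", "q1"),
    change_type = c("behaviour_relevant", "property"),
    trigger_t = c(10, 10)
  )
  pr <- tibble::tibble(t = c(11, 12), side = c("right", "left"))
  m <- match_presses(ev, pr, 4.1)
  expect_true(all(m$outcomes$detected))
  expect_equal(m$outcomes$rt_s, c(1, 2))
  expect_equal(nrow(m$false_alarms), 0)
})

test_that("C2 stops attribution at the next same-side change", {
  ev <- tibble::tibble(
    change_id = c("b1", "b2"),
    change_type = c("behaviour_relevant", "behaviour_irrelevant"),
    trigger_t = c(10, 13)
  )
  # a press after b2's trigger cannot belong to b1 even inside b1's window
  pr <- tibble::tibble(t = 13.5, side = "right")
  m <- match_presses(ev, pr, 10)
  expect_equal(m$outcomes$detected, c(FALSE, TRUE))
  expect_equal(m$outcomes$rt_s, c(NA, 0.5))
})

test_that("ties break to the earliest press and earliest change", {
  ev <- tibble::tibble(
    change_id = "c1", change_type = "property", trigger_t = 10
  )
  pr <- tibble::tibble(t = c(10.5, 11), side = c("left", "left"))
  m <- match_presses(ev, pr, 4.1)
  expect_equal(m$outcomes$rt_s, 0.5)
  expect_equal(m$false_alarms$t, 11)
})

test_that("every press is attributed exactly once or is a false alarm", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      ev <- build_schedule(schedule_spec(group = "A",
        seed = sample.int(1e6, 1)))
      n_pr <- sample(30:120, 1)
      pr <- tibble::tibble(
        t = sort(runif(n_pr, 0, max(ev$trigger_t) + 10)),
        side = sample(c("left", "right"), n_pr, replace = TRUE)
      )
      m <- match_presses(ev, pr, 4.1)
      expect_equal(sum(m$outcomes$detected) + nrow(m$false_alarms), n_pr)
      # each attributed press time appears exactly once
      pt <- m$outcomes$press_t[!is.na(m$outcomes$press_t)]
      expect_equal(anyDuplicated(pt), 0)
      # detected implies RT within [0, cutoff)
      rt <- m$outcomes$rt_s[m$outcomes$detected]
      expect_true(all(rt >= 0 & rt < 4.1))
    }
  })
})

test_that("two-stage coding derives the cutoff then re-matches", {
  ev <- build_schedule(mini_spec(seed = 2))
  s <- simulate_session(default_params(), ev, seed = 3,
    include_gaze = FALSE, include_driving = FALSE)
  res <- code_responses(s$events, s$presses, cutoff_mode = "derive")
  expect_s3_class(res$cutoff, "cb_cutoff")
  expect_identical(res$cutoff$mode, "derived")
  expect_true(res$cutoff$cutoff_s > 0)
  expect_equal(nrow(res$outcomes), nrow(ev))

  resp <- code_responses(s$events, s$presses,
    cutoff_mode = "paper_default")
  expect_equal(resp$cutoff$cutoff_s, 4.1)
})

test_that("detection tables partition trials over the grouping cells", {
  cohort <- simulate_cohort(2, perfect_params(), seed = 5,
    include_gaze = FALSE, include_driving = FALSE)
  oc <- dplyr::bind_rows(lapply(cohort, function(s) {
    m <- match_presses(s$events, s$presses, 4.1)
    dplyr::bind_cols(
      tibble::tibble(participant_id = s$participant_id),
      s$events[, c("change_type", "complexity", "gap_s")],
      m$outcomes["detected"]
    )
  }))
  tab <- detection_table(oc, c("participant_id", "change_type",
    "complexity"))
  expect_true(all(tab$rate_pct == 100))
  # cells partition the 72 changes of each participant
  per <- tapply(tab$n, tab$participant_id, sum)
  expect_true(all(per == 72))
  expect_error(detection_table(oc[0, ]), class = "cb_argument_error")
  expect_error(detection_table(oc, "nope"), class = "cb_argument_error")
})
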