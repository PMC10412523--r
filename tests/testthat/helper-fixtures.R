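# shared small fixtures, all generated in code

# a 6-pair schedule spec for fast end-to-end tests
mini_spec <- function(group = "A", seed = 1) {
  schedule_spec(
    group = group, n_pairs_per_level = 2, gap_levels_s = c(0, 2),
    min_interpair_gap_s = 10, max_interpair_gap_s = 20, seed = seed
  )
}

# deterministic driver: perfect detection, 1 s RT, no noise sources
perfect_params <- function(...) {
  driver_params(
    p_detect = matrix(1, 3, 3,
      dimnames = list(
        c("behaviour_relevant", "behaviour_irrelevant", "property"),
        c("low", "medium", "high")
      )
    ),
    rt_meanlog = 0, rt_sdlog = 0, wrong_button_p = 0,
    false_alarm_rate_per_min = 0, learning_slope = 0, ...
  )
}

p_detect_matrix <- function(p) {
  matrix(p, 3, 3, dimnames = list(
    c("behaviour_relevant", "behaviour_irrelevant", "property"),
    c("low", "medium", "high")
  ))
}

# hand-built outcome table covering every gaze category
toy_outcomes <- function() {
  tibble::tibble(
    participant_id = rep(c("p1", "p2"), each = 4),
    change_id = paste0("c", 1:8),
    change_type = rep(c("behaviour_relevant", "behaviour_irrelevant",
      "property", "property"), 2),
    complexity = rep(c("low", "medium"), each = 4),
    gap_s = rep(c(0, 1, 2, 4), 2),
    encounter_index = rep(1:4, 2),
    detected = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    dwell_pre_ms = c(150, 150, 0, 120, 150, 0, 50, 200),
    dwell_post_ms = c(150, 150, 120, 0, 150, 130, 40, 300)
  ) |>
    dplyr::mutate(
      gaze_category = gaze_category(dwell_pre_ms, dwell_post_ms),
      lbfts = classify_lbfts(detected, dwell_pre_ms, dwell_post_ms)
    )
}
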