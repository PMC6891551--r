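test_that("events on a clean synthetic trial match ground truth within 1 frame", {
  sim <- fixture_sim()
  ev <- fixture_events()
  truth <- sim$truth$events
  for (s in c("L", "R")) {
    expect_length(ev[[s]]$heel_contacts, length(truth[[s]]$heel_contacts))
    expect_length(ev[[s]]$toe_offs, length(truth[[s]]$toe_offs))
    expect_lte(max_event_error(ev[[s]]$heel_contacts, truth[[s]]$heel_contacts), 1)
    expect_lte(max_event_error(ev[[s]]$toe_offs, truth[[s]]$toe_offs), 1)
    expect_true(all(diff(ev[[s]]$heel_contacts) >= 0.4 * ev$fs))
  }
})

test_that("stationary markers raise an insufficient-events error", {
  sim <- fixture_sim()
  frozen <- sim$trial
  frozen$positions <- lapply(frozen$positions, function(m) {
    m[] <- rep(m[1, ], each = nrow(m)); m
  })
  expect_error(detect_events(frozen),
               class = "gaitsym_insufficient_events_error")
})

test_that("event frames are invariant under planar translation", {
  sim <- fixture_sim()
  shifted <- sim$trial
  shifted$positions <- lapply(shifted$positions, function(m) {
    m[, "x"] <- m[, "x"] + 12.3
    m[, "y"] <- m[, "y"] - 4.56
    m
  })
  ev0 <- fixture_events()
  ev1 <- detect_events(preprocess_trial(shifted))
  for (s in c("L", "R")) {
    expect_identical(ev1[[s]]$heel_contacts, ev0[[s]]$heel_contacts)
    expect_identical(ev1[[s]]$toe_offs, ev0[[s]]$toe_offs)
  }
})

test_that("segment_steps assembles alternating steps from toy events", {
  ev <- structure(list(
    L = list(heel_contacts = c(100L, 220L), toe_offs = c(172L)),
    R = list(heel_contacts = c(160L), toe_offs = c(112L, 232L)),
    fs = 100), class = "gait_events")
  steps <- segment_steps(ev)
  expect_equal(nrow(steps), 2)
  expect_equal(steps$leading_foot, c("R", "L"))
  expect_equal(steps$trail_toe_off, c(172L, 232L))
  expect_true(all(steps$trail_heel_contact < steps$lead_heel_contact &
                    steps$lead_heel_contact < steps$trail_toe_off))
})

test_that("a missed contact breaks alternation with a warning, not a patch", {
  ev <- structure(list(
    L = list(heel_contacts = c(100L, 220L, 340L), toe_offs = c(172L, 292L)),
    R = list(heel_contacts = c(160L), toe_offs = c(112L, 232L)),
    fs = 100), class = "gait_events")
  expect_warning(steps <- segment_steps(ev),
                 class = "gaitsym_alternation_warning")
  # the L->L pair is skipped; remaining steps still strictly ordered
  expect_true(all(steps$leading_foot %in% c("L", "R")))
  expect_lt(nrow(steps), 4)
})

test_that("step count respects the event budget and the stride target", {
  sim <- simulate_trial(subject_gait_spec(n_strides = 17), seed = 3)
  ev <- detect_events(preprocess_trial(sim$trial))
  steps <- segment_steps(ev)
  n_hc <- length(ev$L$heel_contacts) + length(ev$R$heel_contacts)
  expect_lte(nrow(steps), n_hc - 1)
  # a trial with >= 16 strides must yield >= 30 usable step intervals
  expect_gte(nrow(steps), 30)
})

test_that("detection survives 0-2 mm marker noise with high sensitivity and precision", {
  hits <- 0; n_true <- 0; n_det <- 0; matched_det <- 0
  for (noise in c(0.001, 0.002)) {
    for (seed in 1:3) {
      sim <- simulate_trial(small_spec(marker_noise_rms = noise), seed = seed)
      ev <- detect_events(preprocess_trial(sim$trial))
      for (s in c("L", "R")) {
        for (type in c("heel_contacts", "toe_offs")) {
          tru <- sim$truth$events[[s]][[type]]
          det <- ev[[s]][[type]]
          n_true <- n_true + length(tru)
          n_det <- n_det + length(det)
          hits <- hits + sum(vapply(tru, function(i) any(abs(det - i) <= 3),
                                    logical(1)))
          matched_det <- matched_det +
            sum(vapply(det, function(i) any(abs(tru - i) <= 3), logical(1)))
        }
      }
    }
  }
  expect_gte(hits / n_true, 0.98)        # sensitivity
  expect_gte(matched_det / n_det, 0.98)  # precision
})
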