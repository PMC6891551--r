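# A minimal hand-built trial: constant heel positions around one step so
# the spatial metrics can be checked by hand arithmetic.
hand_trial <- function() {
  n <- 240
  mk <- function(x, y, z) cbind(x = rep(x, n), y = rep(y, n), z = rep(z, n))
  tr <- trial_trajectories(list(
    L_HEEL = mk(3.200, 0.060, 0.02),
    R_HEEL = mk(2.540, -0.062, 0.03),
    L_TOE = mk(3.350, 0.060, 0.01),
    R_TOE = mk(2.690, -0.062, 0.01)), fs = 100, validate = TRUE)
  attr(tr, "filtered") <- TRUE   # constant series need no smoothing
  tr
}

test_that("step metrics match hand-computed displacements and durations", {
  steps <- data.frame(leading_foot = "L", trail_heel_contact = 60L,
                      lead_heel_contact = 100L, trail_toe_off = 112L)
  rec <- compute_step_metrics(hand_trial(), steps)
  expect_equal(rec$step_length, 3.200 - 2.540, tolerance = 1e-12)
  expect_equal(rec$step_width, 0.060 - (-0.062), tolerance = 1e-12)
  expect_equal(rec$double_support, 0.12, tolerance = 1e-12)
})

test_that("backward steps are dropped with a warning", {
  steps <- data.frame(leading_foot = c("L", "R"),
                      trail_heel_contact = c(60L, 100L),
                      lead_heel_contact = c(100L, 160L),
                      trail_toe_off = c(112L, 172L))
  # R leads at frame 160 but sits behind L: negative length, dropped
  expect_warning(rec <- compute_step_metrics(hand_trial(), steps),
                 class = "gaitsym_step_dropped_warning")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$leading_foot, "L")
})

test_that("the lowest of several in-window minima is selected as MFC", {
  n <- 260
  fs <- 100
  t <- (seq_len(n) - 1) / fs
  # swing from toe off at frame 51 to heel contact at frame 151; two dips:
  # 2.0 cm at 30% swing, 1.2 cm at 60% swing
  toe_z <- rep(0, n)
  sw <- 51:151
  u <- seq(0, 1, length.out = length(sw))
  toe_z[sw] <- 0.05 - 0.03 * exp(-((u - 0.30) / 0.07)^2) -
    0.038 * exp(-((u - 0.60) / 0.07)^2)
  toe_z[sw[1]] <- 0; toe_z[sw[length(sw)]] <- 0
  mk <- function(z) cbind(x = seq(0, 2, length.out = n), y = 0, z = z)
  tr <- trial_trajectories(list(L_HEEL = mk(rep(0, n)), R_HEEL = mk(rep(0, n)),
                                L_TOE = mk(toe_z), R_TOE = mk(rep(0, n))),
                           fs = fs)
  attr(tr, "filtered") <- TRUE
  ev <- structure(list(L = list(heel_contacts = c(40L, 151L), toe_offs = 51L),
                       R = list(heel_contacts = c(1L, 2L), toe_offs = integer(0)),
                       fs = fs), class = "gait_events")
  rec <- compute_mfc(tr, ev, ground_ref = "absolute")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mfc_cm, (0.05 - 0.038) * 100, tolerance = 0.05)
  expect_gt(rec$mfc_frame, 51 + 0.5 * 100)  # the later, lower dip wins
})

test_that("a swing with no interior minimum yields no record and a warning", {
  n <- 260; fs <- 100
  toe_z <- rep(0, n)
  toe_z[51:151] <- seq(0.08, 0.001, length.out = 101)  # monotone descent
  mk <- function(z) cbind(x = seq(0, 2, length.out = n), y = 0, z = z)
  tr <- trial_trajectories(list(L_HEEL = mk(rep(0, n)), R_HEEL = mk(rep(0, n)),
                                L_TOE = mk(toe_z), R_TOE = mk(rep(0, n))),
                           fs = fs)
  attr(tr, "filtered") <- TRUE
  ev <- structure(list(L = list(heel_contacts = c(40L, 151L), toe_offs = 51L),
                       R = list(heel_contacts = c(1L, 2L), toe_offs = integer(0)),
                       fs = fs), class = "gait_events")
  expect_warning(rec <- compute_mfc(tr, ev, ground_ref = "absolute"),
                 class = "gaitsym_swing_skipped_warning")
  expect_equal(nrow(rec), 0)
})

test_that("per-side summary uses the sample (n-1) standard deviation", {
  step_rec <- data.frame(
    leading_foot = rep(c("R", "L"), each = 4),
    step_length = c(0.66, 0.68, 0.64, 0.66, 0.65, 0.65, 0.65, 0.65),
    step_width = rep(0.12, 8), double_support = rep(0.1, 8))
  swing_rec <- data.frame(foot = rep(c("L", "R"), each = 4),
                          mfc_cm = rep(1.5, 8))
  summ <- summarize_subject(step_rec, swing_rec, min_steps = 8)
  row <- summ$parameters[summ$parameters$parameter == "step_length", ]
  expect_equal(row$mean_R, 0.660, tolerance = 1e-9)
  expect_equal(row$sd_R, 0.01632993, tolerance = 1e-6)
  expect_equal(row$sd_L, 0)
  expect_true(summ$included)
  # pooled mean lies between the side means
  expect_gte(row$mean_pooled, min(row$mean_L, row$mean_R))
  expect_lte(row$mean_pooled, max(row$mean_L, row$mean_R))
})

test_that("subjects below the step threshold are flagged, missing sides error", {
  step_rec <- data.frame(
    leading_foot = rep(c("R", "L"), length.out = 29),
    step_length = rep(0.66, 29), step_width = rep(0.12, 29),
    double_support = rep(0.1, 29))
  swing_rec <- data.frame(foot = rep(c("L", "R"), 15), mfc_cm = rep(1.5, 30))
  summ <- summarize_subject(step_rec, swing_rec, min_steps = 30)
  expect_false(summ$included)
  only_r <- step_rec[step_rec$leading_foot == "R", ]
  expect_error(summarize_subject(only_r, swing_rec, min_steps = 10),
               class = "gaitsym_side_missing_error")
})

test_that("noise-free extraction recovers the generator's per-step truth", {
  for (seed in c(2, 5)) {
    sim <- simulate_trial(small_spec(), seed = seed)
    tr <- preprocess_trial(sim$trial)
    ev <- detect_events(tr)
    rec <- compute_step_metrics(tr, segment_steps(ev))
    ts <- sim$truth$steps
    expect_lt(abs(mean(rec$step_length) - mean(ts$step_length)), 0.005)
    expect_lt(abs(mean(rec$step_width) - mean(ts$step_width)), 0.005)
    expect_lt(abs(mean(rec$double_support) - mean(ts$double_support)), 0.010)
    mf <- compute_mfc(tr, ev, ground_ref = "absolute")
    td <- sim$truth$swings[sim$truth$swings$detectable, ]
    expect_lt(abs(mean(mf$mfc_cm) - mean(td$mfc_cm)), 0.05)
  }
})

test_that("step metrics are invariant under rigid translation and y reflection", {
  sim <- fixture_sim()
  tr <- fixture_filtered()
  ev <- fixture_events()
  steps <- segment_steps(ev)
  rec0 <- compute_step_metrics(tr, steps)
  moved <- tr
  moved$positions <- lapply(moved$positions, function(m) {
    m[, "x"] <- m[, "x"] + 3; m[, "y"] <- -m[, "y"]; m
  })
  rec1 <- compute_step_metrics(moved, steps)
  expect_equal(rec1$step_length, rec0$step_length, tolerance = 1e-12)
  expect_equal(rec1$step_width, rec0$step_width, tolerance = 1e-12)
})
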