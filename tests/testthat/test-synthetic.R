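test_that("the generator is deterministic given a seed", {
  a <- simulate_trial(small_spec(marker_noise_rms = 0.001), seed = 42)
  b <- simulate_trial(small_spec(marker_noise_rms = 0.001), seed = 42)
  c <- simulate_trial(small_spec(marker_noise_rms = 0.001), seed = 43)
  expect_identical(a$trial$positions, b$trial$positions)
  expect_identical(a$truth$steps, b$truth$steps)
  expect_false(identical(a$trial$positions, c$trial$positions))
})

test_that("invalid specifications are rejected", {
  expect_error(subject_gait_spec(mfc_cm = c(L = -1, R = 1)),
               class = "gaitsym_spec_error")
  expect_error(subject_gait_spec(toe_peak_early = 0.01),
               class = "gaitsym_spec_error")  # peak below clearance
  expect_error(subject_gait_spec(n_strides = 1), class = "gaitsym_spec_error")
  expect_error(subject_gait_spec(cadence = 200, double_support = c(L = .3, R = .3)),
               class = "gaitsym_spec_error")  # no room for swing
  expect_error(cohort_spec(n_subjects = 1), class = "gaitsym_spec_error")
})

test_that("every generated swing has one clearance minimum inside 20-80%", {
  sim <- fixture_sim()
  toe <- sim$trial$positions$L_TOE[, "z"]
  sw <- sim$truth$swings
  sw <- sw[sw$foot == "L", ]
  for (k in seq_len(nrow(sw))) {
    span <- sw$heel_contact[k] - sw$toe_off[k]
    win <- (sw$toe_off[k] + round(0.2 * span)):(sw$toe_off[k] + round(0.8 * span))
    expect_equal(count_min_regions(toe[win]), 1)
  }
})

test_that("ground-truth step values are internally consistent", {
  sim <- fixture_sim()
  ts <- sim$truth$steps
  expect_true(all(ts$trail_heel_contact < ts$lead_heel_contact))
  expect_true(all(ts$lead_heel_contact < ts$trail_toe_off))
  expect_true(all(ts$step_length > 0 & ts$step_width > 0 &
                    ts$double_support > 0))
  expect_true(all(ts$leading_foot[-1] != ts$leading_foot[-nrow(ts)]))
  # programmed clearance values sit inside the physical bounds
  expect_true(all(sim$truth$swings$mfc_cm > 0 &
                    sim$truth$swings$mfc_cm < 5))
})

test_that("programmed left-right clearance asymmetry is recovered end to end", {
  spec <- subject_gait_spec(mfc_cm = c(L = 2.0, R = 1.0), n_strides = 12)
  sim <- simulate_trial(spec, seed = 9)
  f <- extract_features(list(S1 = sim$trial),
                        pipeline_config(min_steps = 10, ground_ref = "absolute"))
  expect_equal(f$mfc_si_mean, symmetry_index(1.0, 2.0), tolerance = 2)
  # a symmetric repeatable subject shows near-zero mean SI (SD-based SI
  # is undefined noise for a walker with no stride-to-stride variability;
  # double support tolerates frame quantization of the ~0.1 s interval at
  # 100 Hz)
  sym <- simulate_trial(deterministic_spec(), seed = 5)
  fs <- extract_features(list(S1 = sym$trial),
                         pipeline_config(min_steps = 10, ground_ref = "absolute"))
  for (col in c("step_length_si_mean", "step_width_si_mean", "mfc_si_mean"))
    expect_lt(fs[[col]], 1)
  expect_lt(fs$double_support_si_mean, 8)
})

test_that("cohorts reproduce bit-for-bit and respect GHQ bounds", {
  cs <- small_cohort_spec(n_subjects = 4)
  a <- simulate_cohort(cs, seed = 17)
  b <- simulate_cohort(cs, seed = 17)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ghq, b$ghq)
  totals <- score_ghq12(a$ghq)$ghq_total
  expect_true(all(totals >= 0 & totals <= 12))
  expect_equal(nrow(a$subjects), 4)
  expect_true(all(a$subjects$age >= 50))
})

test_that("stronger latent coupling raises the cohort SI correlation", {
  # grid stays below the baseline asymmetry so the folded |base + beta*m|
  # model remains monotone in the latent score
  grid <- c(0, 0.02, 0.06)
  mean_r <- vapply(grid, function(b) {
    rs <- vapply(1:4, function(seed) {
      cs <- small_cohort_spec(
        n_subjects = 36, n_strides = 10,
        beta = c(step_length = b, step_width = b, double_support = b, mfc = b),
        beta_sd = null_beta, asym_noise = 0.02)
      co <- simulate_cohort(cs, seed = 300 + seed)
      f <- extract_features(co, pipeline_config(min_steps = 10))
      tab <- merge(f, score_ghq12(co$ghq), by = "subject_id")
      cor(tab$step_length_si_mean, tab$ghq_total)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})
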