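# Shared fixtures. Everything is generated in code; small stride counts
# keep the unit tests fast, while the acceptance tests use the full-size
# study conditions.

small_spec <- function(...) subject_gait_spec(n_strides = 8, ...)

# all stochastic terms off: a perfectly repeatable walker
deterministic_spec <- function(...) {
  subject_gait_spec(step_length_sd = c(L = 0, R = 0),
                    step_width_sd = c(L = 0, R = 0),
                    double_support_sd = c(L = 0, R = 0),
                    mfc_sd_cm = c(L = 0, R = 0),
                    step_time_sd = 0, n_strides = 8, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# one cached small simulated trial reused by read-only tests
fixture_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_trial(small_spec(), seed = 101)
  .fixture_env$sim
}

fixture_filtered <- function() {
  if (is.null(.fixture_env$filtered))
    .fixture_env$filtered <- preprocess_trial(fixture_sim()$trial)
  .fixture_env$filtered
}

fixture_events <- function() {
  if (is.null(.fixture_env$events))
    .fixture_env$events <- detect_events(fixture_filtered())
  .fixture_env$events
}

max_event_error <- function(detected, truth) {
  max(vapply(detected, function(i) min(abs(truth - i)), numeric(1)))
}

# small config for unit tests of the pipeline (8 strides ~ 14 steps)
small_config <- function(...) pipeline_config(min_steps = 10, ...)

# a null / coupled cohort scaled down for unit tests
small_cohort_spec <- function(n_subjects = 12, n_strides = 8, ...) {
  cohort_spec(n_subjects = n_subjects,
              base_spec = subject_gait_spec(n_strides = n_strides,
                                            marker_noise_rms = 0.001),
              ...)
}

null_beta <- c(step_length = 0, step_width = 0, double_support = 0, mfc = 0)

# independent count of interior local-minimum regions (plateau = one
# region), used to check the generated swing shape
count_min_regions <- function(z) {
  s <- sign(diff(z))
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-length(s)] == -1 & s[-1] == 1)
}

# write a csv_wide marker file directly (bypassing write_marker_table's
# validation) so gap-handling on read can be exercised with NA runs
write_csv_na <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g,units=m", trial$fs), con)
  tab <- data.frame(frame = seq_len(trial$frames))
  for (m in c("L_HEEL", "R_HEEL", "L_TOE", "R_TOE"))
    for (ax in c("x", "y", "z"))
      tab[[paste0(gsub("_", "", m), "_", ax)]] <- trial$positions[[m]][, ax]
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
}
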