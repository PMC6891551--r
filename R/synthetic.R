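# Synthetic gait generator.
#
# Trajectories are built as piecewise quintic-smoothstep curves through
# physiologic control points, so every event time, step placement and
# swing clearance is known exactly by construction:
#   * heel height: symmetric dip to 0 at each heel contact, a large bump
#     during swing;
#   * toe height: flat during stance, small pre-toe-off dip reaching 0 at
#     toe off, early-swing peak, a flat mid-swing clearance plateau, a
#     higher late-swing peak, 0 at the next heel contact;
#   * anterior positions: hold during stance, smoothstep advance during
#     swing; mediolateral positions change at each landing.
#
# The mid-swing clearance plateau is depth-calibrated so that the minimum
# of the zero-phase 6 Hz Butterworth-filtered toe height equals the
# programmed MFC: reported clearance values are post-filter observables,
# so the generator programs the observable, not the raw marker minimum.

#' Per-subject gait specification for the synthetic generator
#'
#' Defaults describe a healthy older adult walking at preferred pace:
#' step length 0.657 m, step width 0.121 m, double support 0.099 s, MFC
#' 1.667 cm, cadence 110 steps/min, with stride-to-stride SDs matching
#' typical intra-subject variability. All sided parameters take a
#' `c(L = , R = )` pair.
#'
#' @param step_length,step_length_sd per-side step length mean / SD (m).
#' @param step_width,step_width_sd per-side step width mean / SD (m).
#' @param double_support,double_support_sd per-side double support mean /
#'   SD (s), attributed to the leading foot.
#' @param mfc_cm,mfc_sd_cm per-side minimum foot clearance mean / SD (cm).
#' @param cadence steps per minute.
#' @param step_time_sd stride-to-stride SD of the step duration (s).
#' @param toe_peak_early,toe_peak_late early/late swing toe height peaks
#'   (m); both must exceed the largest programmed clearance so the swing
#'   curve always has an interior minimum.
#' @param marker_noise_rms white marker noise RMS added to every
#'   coordinate (m); 0 for noise-free trajectories.
#' @param n_strides number of full stride cycles (>= 2; the cohort
#'   protocol requires at least 30 step cycles, i.e. the default 30
#'   strides yields ~58 usable steps).
#' @param fs sampling rate (Hz).
#' @param foot_length anterior offset of the toe marker from the heel (m).
#' @return a `subject_gait_spec` object.
#' @export
subject_gait_spec <- function(step_length = c(L = 0.657, R = 0.657),
                              step_length_sd = c(L = 0.036, R = 0.036),
                              step_width = c(L = 0.121, R = 0.121),
                              step_width_sd = c(L = 0.030, R = 0.030),
                              double_support = c(L = 0.099, R = 0.099),
                              double_support_sd = c(L = 0.019, R = 0.019),
                              mfc_cm = c(L = 1.667, R = 1.667),
                              mfc_sd_cm = c(L = 0.447, R = 0.447),
                              cadence = 110,
                              step_time_sd = 0.01,
                              toe_peak_early = 0.05,
                              toe_peak_late = 0.10,
                              marker_noise_rms = 0,
                              n_strides = 30,
                              fs = 100,
                              foot_length = 0.15) {
  pair <- function(x) {
    if (length(x) == 1) x <- c(L = unname(x), R = unname(x))
    if (is.null(names(x))) names(x) <- c("L", "R")
    x[c("L", "R")]
  }
  spec <- structure(list(
    step_length = pair(step_length), step_length_sd = pair(step_length_sd),
    step_width = pair(step_width), step_width_sd = pair(step_width_sd),
    double_support = pair(double_support),
    double_support_sd = pair(double_support_sd),
    mfc_cm = pair(mfc_cm), mfc_sd_cm = pair(mfc_sd_cm),
    cadence = cadence, step_time_sd = step_time_sd,
    toe_peak_early = toe_peak_early, toe_peak_late = toe_peak_late,
    marker_noise_rms = marker_noise_rms, n_strides = as.integer(n_strides),
    fs = fs, foot_length = foot_length), class = "subject_gait_spec")
  validate_gait_spec(spec)
  spec
}

validate_gait_spec <- function(spec) {
  bad <- function(msg) stop_gaitsym(msg, "gaitsym_spec_error")
  if (any(spec$step_length <= 0) || any(spec$step_width <= 0) ||
      any(spec$double_support <= 0) || spec$cadence <= 0)
    bad("step lengths, widths, double support and cadence must be positive")
  if (any(spec$mfc_cm <= 0)) bad("programmed MFC must be positive")
  if (spec$toe_peak_early * 100 <= max(spec$mfc_cm) ||
      spec$toe_peak_late * 100 <= max(spec$mfc_cm))
    bad("swing toe peaks must exceed the programmed clearance")
  if (spec$n_strides < 2) bad("n_strides must be >= 2")
  step_time <- 60 / spec$cadence
  if (step_time - max(spec$double_support) < 0.25)
    bad("swing duration too short: increase step time or reduce double support")
  if (spec$fs <= 0) bad("fs must be positive")
  invisible(spec)
}

#' Simulate one walking trial with exact ground truth
#'
#' Generates marker trajectories for a single overground pass following a
#' [subject_gait_spec()], together with the ground truth every pipeline
#' stage can be validated against: event frames, per-step spatiotemporal
#' values, and per-swing clearance (value and frame).
#'
#' @param spec a [subject_gait_spec()].
#' @param seed integer seed; the same seed reproduces the trial bit for
#'   bit.
#' @param subject_id,trial_id identifiers for the emitted trial.
#' @return list with elements `trial` (a [trial_trajectories()]) and
#'   `truth` (list: `events`, `steps`, `swings`, `side_means`).
#' @export
simulate_trial <- function(spec, seed = 1, subject_id = "S1", trial_id = "T1") {
  validate_gait_spec(spec)
  with_seed(seed, simulate_trial_impl(spec, subject_id, trial_id))
}

simulate_trial_impl <- function(spec, subject_id, trial_id) {
  fs <- spec$fs
  N <- 2L * spec$n_strides          # steps; lead foot alternates L, R, ...
  lead <- rep(c("L", "R"), length.out = N)
  tau_base <- 60 / spec$cadence

  # --- temporal schedule -------------------------------------------------
  tau <- pmax(0.35, pmin(0.8, rnorm(N, tau_base, spec$step_time_sd)))
  t_hc <- 0.8 + c(0, cumsum(tau[-1]))          # heel contact of step k
  ds <- rnorm(N, spec$double_support[lead], spec$double_support_sd[lead])
  up <- c(tau[-1] - 0.25, Inf)                 # trailing swing must be >= 0.25 s
  ds <- pmax(0.04, pmin(ds, up))

  # --- spatial schedule --------------------------------------------------
  sl <- pmax(0.1, rnorm(N, spec$step_length[lead], spec$step_length_sd[lead]))
  X <- cumsum(sl)                              # landing x of step k (X0 = 0)
  w <- pmax(0.02, rnorm(N, spec$step_width[lead], spec$step_width_sd[lead]))
  y0 <- c(L = spec$step_width[["L"]] / 2, R = -spec$step_width[["R"]] / 2)
  # landing y of step k sits w[k] lateral of the trailing foot's position
  # (the landing of step k-1); left lands to the left (+y), right to the
  # right (-y)
  Y <- numeric(N)
  for (k in seq_len(N)) {
    trail_y <- if (k == 1) y0[["R"]] else Y[k - 1]
    Y[k] <- trail_y + if (lead[k] == "L") w[k] else -w[k]
  }

  # --- per-foot swing lists ----------------------------------------------
  swing_pre <- tau_base - mean(spec$double_support)   # nominal swing duration
  feet <- list()
  for (side in c("L", "R")) {
    ks <- which(lead == side)                  # this foot's landing steps
    sw <- list()
    for (j in seq_along(ks)) {
      k <- ks[j]
      if (j == 1) {
        to_t <- if (k == 1) t_hc[1] - swing_pre else t_hc[k - 1] + ds[k - 1]
        x_from <- 0
        y_from <- y0[[side]]
        detectable <- FALSE                    # no preceding same-foot HC
      } else {
        to_t <- t_hc[k - 1] + ds[k - 1]        # foot trails step k-1
        x_from <- X[k - 2]
        y_from <- Y[k - 2]
        detectable <- TRUE
      }
      sw[[j]] <- list(to = to_t, hc = t_hc[k], x_from = x_from, x_to = X[k],
                      y_from = y_from, y_to = Y[k], detectable = detectable,
                      mfc = max(0.002, min(spec$toe_peak_early - 0.005,
                        rnorm(1, spec$mfc_cm[[side]] / 100,
                              spec$mfc_sd_cm[[side]] / 100))))
    }
    feet[[side]] <- sw
  }

  n_frames <- round((t_hc[N] + 0.6) * fs)
  tt <- (seq_len(n_frames) - 1) / fs
  fspec <- filter_spec(cutoff_hz = 6, order = 4, fs = fs)

  positions <- list()
  truth_swings <- list(L = NULL, R = NULL)
  for (side in c("L", "R")) {
    sw <- feet[[side]]
    # heel height knots
    hk <- c(sw[[1]]$to - 0.30); hv <- c(0)
    for (s in sw) {
      D <- s$hc - s$to
      hk <- c(hk, s$to - 0.10, s$to, s$to + 0.35 * D,
              s$hc - 0.12, s$hc - 0.05, s$hc, s$hc + 0.05, s$hc + 0.12)
      hv <- c(hv, 0.03, 0.05, 0.16, 0.02, 0.008, 0, 0.008, 0.02)
    }
    heel_z <- interp_knots(hk, hv, tt)

    # toe height knots with calibrated clearance plateau
    build_toe <- function(dips) {
      tk <- c(sw[[1]]$to - 0.20); tv <- c(0)
      for (j in seq_along(sw)) {
        s <- sw[[j]]; D <- s$hc - s$to
        # pre/post toe-off dip knots at fixed offsets so the lift-off
        # velocity profile is locally symmetric about the toe-off instant
        # regardless of swing duration (keeps the detected zero crossing
        # unbiased)
        tk <- c(tk, s$to - 0.14, s$to - 0.06, s$to, s$to + 0.058,
                s$to + 0.30 * D, s$to + 0.45 * D, s$to + 0.65 * D,
                s$to + 0.87 * D, s$hc)
        tv <- c(tv, 0, 0.004, 0, 0.004, spec$toe_peak_early,
                dips[j], dips[j], spec$toe_peak_late, 0)
      }
      interp_knots(tk, tv, tt)
    }
    target <- vapply(sw, function(s) s$mfc, numeric(1))
    dips <- target
    for (iter in 1:3) {
      toe_z <- build_toe(dips)
      toe_f <- lowpass_filter(toe_z, fspec)
      for (j in seq_along(sw)) {
        s <- sw[[j]]; D <- s$hc - s$to
        win <- (round((s$to + 0.35 * D) * fs) + 1):(round((s$to + 0.75 * D) * fs) + 1)
        dips[j] <- dips[j] + (target[j] - min(toe_f[win]))
      }
    }
    toe_z <- build_toe(dips)
    toe_f <- lowpass_filter(toe_z, fspec)
    mfc_frames <- integer(length(sw))
    for (j in seq_along(sw)) {
      s <- sw[[j]]; D <- s$hc - s$to
      win <- (round((s$to + 0.35 * D) * fs) + 1):(round((s$to + 0.75 * D) * fs) + 1)
      mfc_frames[j] <- win[which.min(toe_f[win])]
    }
    truth_swings[[side]] <- data.frame(
      foot = side,
      toe_off = vapply(sw, function(s) as.integer(round(s$to * fs)) + 1L, integer(1)),
      heel_contact = vapply(sw, function(s) as.integer(round(s$hc * fs)) + 1L, integer(1)),
      mfc_cm = target * 100,
      mfc_frame = mfc_frames,
      detectable = vapply(sw, function(s) s$detectable, logical(1)))

    # planar knots: hold during stance, advance during swing. The last
    # 4 mm of the anterior advance take the final 100 ms (a soft landing):
    # the main advance then completes early enough that its filter
    # ringing has decayed at the contact instant, keeping heel positions
    # read at heel contact unbiased.
    xk <- unlist(lapply(sw, function(s) c(s$to, s$hc - 0.10, s$hc)))
    xv <- unlist(lapply(sw, function(s) c(s$x_from, s$x_to - 0.004, s$x_to)))
    yv <- unlist(lapply(sw, function(s) c(s$y_from, s$y_to, s$y_to)))
    heel_x <- interp_knots(xk, xv, tt)
    heel_y <- interp_knots(xk, yv, tt)

    positions[[paste0(side, "_HEEL")]] <- cbind(x = heel_x, y = heel_y, z = heel_z)
    positions[[paste0(side, "_TOE")]] <- cbind(x = heel_x + spec$foot_length,
                                               y = heel_y, z = toe_z)
  }

  if (spec$marker_noise_rms > 0)
    positions <- lapply(positions, function(m)
      m + rnorm(length(m), 0, spec$marker_noise_rms))

  trial <- trial_trajectories(positions, fs = fs, subject_id = subject_id,
                              trial_id = trial_id)

  # --- ground truth ------------------------------------------------------
  fr <- function(t) as.integer(round(t * fs)) + 1L
  events <- list(fs = fs)
  for (side in c("L", "R")) {
    sw <- feet[[side]]
    events[[side]] <- list(
      heel_contacts = vapply(sw, function(s) fr(s$hc), integer(1)),
      toe_offs = vapply(sw[vapply(sw, function(s) s$detectable, logical(1))],
                        function(s) fr(s$to), integer(1)))
  }
  ks <- 2:(N - 1)
  steps <- data.frame(
    leading_foot = lead[ks],
    trail_heel_contact = fr(t_hc[ks - 1]),
    lead_heel_contact = fr(t_hc[ks]),
    trail_toe_off = fr(t_hc[ks] + ds[ks]),
    step_length = sl[ks],
    step_width = abs(Y[ks] - Y[ks - 1]),
    double_support = ds[ks])
  side_means <- data.frame(
    parameter = GAIT_PARAMETERS,
    L = c(spec$step_length[["L"]], spec$step_width[["L"]],
          spec$double_support[["L"]], spec$mfc_cm[["L"]]),
    R = c(spec$step_length[["R"]], spec$step_width[["R"]],
          spec$double_support[["R"]], spec$mfc_cm[["R"]]))
  list(trial = trial,
       truth = list(events = events, steps = steps,
                    swings = rbind(truth_swings$L, truth_swings$R),
                    side_means = side_means))
}

#' Cohort specification for the synthetic generator
#'
#' Defines a cohort in which a latent mental-health burden score couples
#' to gait asymmetry and to GHQ-12 item responses. For each subject a
#' latent score `m ~ N(0, 1)` is drawn; each gait parameter's relative
#' left-right asymmetry is `base + beta * m + noise` (folded at 0, with a
#' random sign deciding which side is larger), applied separately to the
#' per-side means (`asym_base`, `beta`) and to the per-side
#' stride-to-stride SDs (`asym_sd_base`, `beta_sd`). GHQ-12 items are
#' Bernoulli with agree-probability `plogis(ghq_intercept + ghq_slope*m)`;
#' the default intercept/slope are calibrated so simulated totals have
#' mean ~1.56 and SD ~2.08 with a relatively healthy cohort.
#'
#' Baseline asymmetries default to the magnitudes typical of healthy
#' older walkers (5.9% / 14.8% / 9.7% / 25.7% for step length, step
#' width, double support and MFC means; 33-37% for their SDs); default
#' couplings are calibrated per parameter (features whose sample means
#' and SDs carry more finite-sample noise over ~30 strides get stronger
#' coupling) to produce moderate-to-strong positive correlations
#' (r ~ 0.4-0.55) between GHQ-12 totals and extracted SI features, the
#' effect-size regime the pipeline is designed to resolve.
#'
#' @param n_subjects cohort size (default 126).
#' @param base_spec a [subject_gait_spec()] shared by all subjects before
#'   asymmetry is applied.
#' @param asym_base,asym_sd_base named baseline asymmetry fractions per
#'   parameter for means and SDs.
#' @param beta,beta_sd named coupling coefficients (asymmetry fraction per
#'   latent SD); set to 0 for a null cohort.
#' @param asym_noise,asym_sd_noise subject-level SD of the asymmetry
#'   around its latent prediction.
#' @param ghq_intercept,ghq_slope logistic item-response parameters.
#' @param age_mean,age_sd,age_range cohort age distribution (years).
#' @param prop_male proportion of male participants.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 126,
                        base_spec = subject_gait_spec(marker_noise_rms = 0.001),
                        asym_base = c(step_length = 0.059, step_width = 0.148,
                                      double_support = 0.097, mfc = 0.257),
                        asym_sd_base = c(step_length = 0.354, step_width = 0.367,
                                         double_support = 0.339, mfc = 0.324),
                        beta = c(step_length = 0.045, step_width = 0.065,
                                 double_support = 0.055, mfc = 0.07),
                        beta_sd = c(step_length = 0.20, step_width = 0.20,
                                    double_support = 0.20, mfc = 0.20),
                        asym_noise = 0.045,
                        asym_sd_noise = 0.10,
                        ghq_intercept = -2.536,
                        ghq_slope = 1.444,
                        age_mean = 66.2, age_sd = 8.38,
                        age_range = c(50, 95),
                        prop_male = 30 / 126) {
  full <- function(x) {
    if (length(x) == 1) x <- setNames(rep(x, 4), GAIT_PARAMETERS)
    x[GAIT_PARAMETERS]
  }
  spec <- structure(list(
    n_subjects = as.integer(n_subjects), base_spec = base_spec,
    asym_base = full(asym_base), asym_sd_base = full(asym_sd_base),
    beta = full(beta), beta_sd = full(beta_sd),
    asym_noise = asym_noise, asym_sd_noise = asym_sd_noise,
    ghq_intercept = ghq_intercept, ghq_slope = ghq_slope,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    prop_male = prop_male), class = "cohort_spec")
  if (spec$n_subjects < 2)
    stop_gaitsym("n_subjects must be >= 2", "gaitsym_spec_error")
  if (any(spec$beta < 0) || any(spec$beta_sd < 0))
    stop_gaitsym("coupling coefficients must be nonnegative",
                 "gaitsym_spec_error")
  validate_gait_spec(base_spec)
  spec
}

# Fold an asymmetry draw at 0 and cap so per-side values stay positive.
fold_asym <- function(x) pmin(abs(x), 1.4)

#' Simulate a cohort of walking trials plus GHQ-12 responses
#'
#' Every subject gets an independent RNG stream derived from `seed`, so a
#' cohort is reproducible bit for bit and individual subjects can be
#' regenerated in isolation.
#'
#' @param cohort a [cohort_spec()].
#' @param seed integer base seed.
#' @return a `synthetic_cohort`: list with `trials` (named list of
#'   [trial_trajectories()]), `ghq` (item responses, `ghq_responses`),
#'   `subjects` (data.frame: `subject_id, age, sex, latent`), `truth`
#'   (per-subject ground truth plus programmed SI features `si_true`),
#'   and the generating `spec` and `seed`.
#' @export
simulate_cohort <- function(cohort, seed = 1) {
  n <- cohort$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  trials <- list()
  per_subject <- list()
  ghq_rows <- list()
  subj_rows <- list()
  si_rows <- list()
  for (i in seq_len(n)) {
    s_i <- subject_seed(seed, i)
    res <- with_seed(s_i, {
      m <- rnorm(1)
      a_mean <- fold_asym(cohort$asym_base + cohort$beta * m +
                            rnorm(4, 0, cohort$asym_noise))
      a_sd <- fold_asym(cohort$asym_sd_base + cohort$beta_sd * m +
                          rnorm(4, 0, cohort$asym_sd_noise))
      sgn_mean <- sample(c(-1, 1), 4, replace = TRUE)
      sgn_sd <- sample(c(-1, 1), 4, replace = TRUE)
      side_pair <- function(base, a, s) {
        a <- unname(a); s <- unname(s)
        c(L = base * (1 - s * a / 2), R = base * (1 + s * a / 2))
      }
      bs <- cohort$base_spec
      base_of <- function(field) mean(bs[[field]])
      sd_field <- c(step_length = "step_length_sd", step_width = "step_width_sd",
                    double_support = "double_support_sd", mfc = "mfc_sd_cm")
      mean_field <- c(step_length = "step_length", step_width = "step_width",
                      double_support = "double_support", mfc = "mfc_cm")
      spec_args <- list(
        cadence = bs$cadence, step_time_sd = bs$step_time_sd,
        toe_peak_early = bs$toe_peak_early, toe_peak_late = bs$toe_peak_late,
        marker_noise_rms = bs$marker_noise_rms, n_strides = bs$n_strides,
        fs = bs$fs, foot_length = bs$foot_length)
      for (p in GAIT_PARAMETERS) {
        k <- match(p, GAIT_PARAMETERS)
        spec_args[[mean_field[[p]]]] <-
          side_pair(base_of(mean_field[[p]]), a_mean[k], sgn_mean[k])
        spec_args[[sd_field[[p]]]] <-
          side_pair(base_of(sd_field[[p]]), a_sd[k], sgn_sd[k])
      }
      spec_i <- do.call(subject_gait_spec, spec_args)
      p_agree <- plogis(cohort$ghq_intercept + cohort$ghq_slope * m)
      agree <- rbinom(12, 1, p_agree)
      items <- ifelse(agree == 1, sample(2:3, 12, replace = TRUE),
                      sample(0:1, 12, replace = TRUE))
      age <- min(max(rnorm(1, cohort$age_mean, cohort$age_sd),
                     cohort$age_range[1]), cohort$age_range[2])
      sex <- sample(c("M", "F"), 1,
                    prob = c(cohort$prop_male, 1 - cohort$prop_male))
      trial_seed <- subject_seed(s_i, 7919)
      sim <- simulate_trial(spec_i, seed = trial_seed, subject_id = ids[i])
      list(m = m, a_mean = a_mean, a_sd = a_sd, items = items,
           age = age, sex = sex, sim = sim)
    })
    trials[[ids[i]]] <- res$sim$trial
    per_subject[[ids[i]]] <- res$sim$truth
    ghq_rows[[i]] <- c(subject_id = ids[i],
                       setNames(res$items, sprintf("item%02d", 1:12)))
    subj_rows[[i]] <- data.frame(subject_id = ids[i], age = res$age,
                                 sex = res$sex, latent = res$m)
    si_rows[[i]] <- data.frame(
      subject_id = ids[i],
      t(setNames(c(res$a_mean * 100, res$a_sd * 100),
                 c(paste0("si_mean_", GAIT_PARAMETERS),
                   paste0("si_sd_", GAIT_PARAMETERS)))))
  }
  ghq <- as.data.frame(do.call(rbind, ghq_rows), stringsAsFactors = FALSE)
  for (cl in sprintf("item%02d", 1:12)) ghq[[cl]] <- as.integer(ghq[[cl]])
  class(ghq) <- c("ghq_responses", "data.frame")
  structure(list(
    trials = trials, ghq = ghq,
    subjects = do.call(rbind, subj_rows),
    truth = list(per_subject = per_subject,
                 si_true = do.call(rbind, si_rows)),
    spec = cohort, seed = seed), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, seed %s\n",
              length(x$trials), format(x$seed)))
  invisible(x)
}
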