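# Spatiotemporal parameters per step and per swing, and their per-subject
# summaries. Definitions:
#   step length  = anterior (x) displacement between the heels at the
#                  leading foot's heel contact [m]
#   step width   = absolute mediolateral (y) heel-heel displacement at the
#                  same instant [m]
#   double support = leading heel contact to trailing-foot toe off [s]
#   MFC          = minimum vertical clearance of the toe above the walking
#                  surface during mid-swing [cm]

#' Compute step length, step width and double-support time
#'
#' @param trial a filtered [trial_trajectories()] (unfiltered input is
#'   filtered with the default [filter_spec()]).
#' @param steps step intervals from [segment_steps()].
#' @return data.frame with one row per step: `leading_foot`, `frame`,
#'   `step_length`, `step_width`, `double_support`. Steps with negative
#'   length (backward step or detection fault) are dropped with a warning.
#' @export
compute_step_metrics <- function(trial, steps) {
  trial <- ensure_filtered(trial)
  fs <- trial$fs
  lead_heel <- ifelse(steps$leading_foot == "L", "L_HEEL", "R_HEEL")
  trail_heel <- ifelse(steps$leading_foot == "L", "R_HEEL", "L_HEEL")
  n <- nrow(steps)
  sl <- sw <- numeric(n)
  for (i in seq_len(n)) {
    f <- steps$lead_heel_contact[i]
    sl[i] <- trial$positions[[lead_heel[i]]][f, "x"] -
      trial$positions[[trail_heel[i]]][f, "x"]
    sw[i] <- abs(trial$positions[[lead_heel[i]]][f, "y"] -
                   trial$positions[[trail_heel[i]]][f, "y"])
  }
  ds <- (steps$trail_toe_off - steps$lead_heel_contact) / fs
  rec <- data.frame(leading_foot = steps$leading_foot,
                    frame = steps$lead_heel_contact,
                    step_length = sl, step_width = sw, double_support = ds)
  bad <- rec$step_length <= 0
  if (any(bad)) {
    warn_gaitsym(sprintf("%d step(s) dropped: non-positive step length",
                         sum(bad)), "gaitsym_step_dropped_warning")
    rec <- rec[!bad, ]
  }
  rec
}

#' Compute minimum foot clearance per swing
#'
#' For each swing (toe off to the next same-foot heel contact), searches
#' the window spanning 20-80% of the swing for local minima of the
#' filtered toe height and takes the lowest, minus a ground reference.
#' Swings with no interior local minimum yield no record (warning);
#' swings shorter than 10 frames are skipped (warning).
#'
#' @param trial a filtered [trial_trajectories()].
#' @param events a `gait_events` object from [detect_events()].
#' @param ground_ref `"midstance"` (default): per-foot median toe height
#'   over the middle of each stance phase, a foot-flat proxy that removes
#'   the shoe/marker offset; `"absolute"`: use toe height directly
#'   (appropriate when the walking surface is exactly z = 0, as in
#'   synthetic data).
#' @param window fraction of the swing searched, default `c(0.2, 0.8)`.
#' @return data.frame with one row per swing: `foot`, `mfc_cm`,
#'   `mfc_frame`, `toe_off`, `heel_contact`.
#' @export
compute_mfc <- function(trial, events, ground_ref = c("midstance", "absolute"),
                        window = c(0.2, 0.8)) {
  ground_ref <- match.arg(ground_ref)
  trial <- ensure_filtered(trial)
  out_foot <- character(0); out_mfc <- numeric(0)
  out_frame <- out_to <- out_hc <- integer(0)
  skipped_short <- 0L
  skipped_nomin <- 0L
  for (side in c("L", "R")) {
    toe_z <- trial$positions[[paste0(side, "_TOE")]][, "z"]
    hc <- events[[side]]$heel_contacts
    to <- events[[side]]$toe_offs
    ref <- if (ground_ref == "absolute") 0 else
      midstance_toe_reference(toe_z, hc, to)
    for (t0 in to) {
      nxt <- hc[hc > t0]
      if (!length(nxt)) next
      t1 <- nxt[1]
      if (t1 - t0 < 10) {
        skipped_short <- skipped_short + 1L
        next
      }
      win <- (t0 + round(window[1] * (t1 - t0))):(t0 + round(window[2] * (t1 - t0)))
      mins <- win[local_minima(toe_z[win])]
      if (!length(mins)) {
        skipped_nomin <- skipped_nomin + 1L
        next
      }
      best <- mins[which.min(toe_z[mins])]
      out_foot <- c(out_foot, side)
      out_mfc <- c(out_mfc, (toe_z[best] - ref) * 100)
      out_frame <- c(out_frame, best)
      out_to <- c(out_to, t0)
      out_hc <- c(out_hc, t1)
    }
  }
  if (skipped_short > 0)
    warn_gaitsym(sprintf("%d swing(s) skipped: shorter than 10 frames",
                         skipped_short), "gaitsym_swing_skipped_warning")
  if (skipped_nomin > 0)
    warn_gaitsym(sprintf("%d swing(s) skipped: no interior toe-height minimum",
                         skipped_nomin), "gaitsym_swing_skipped_warning")
  data.frame(foot = out_foot, mfc_cm = out_mfc, mfc_frame = out_frame,
             toe_off = out_to, heel_contact = out_hc)
}

# Median toe height over the central portion of each stance phase
# (heel contact to the same foot's next toe off): a foot-flat reference
# for clearance when the floor height is unknown.
midstance_toe_reference <- function(toe_z, heel_contacts, toe_offs) {
  vals <- c()
  for (h in heel_contacts) {
    nxt <- toe_offs[toe_offs > h]
    if (!length(nxt)) next
    t1 <- nxt[1]
    if (t1 - h < 10) next
    mid <- (h + round(0.3 * (t1 - h))):(h + round(0.7 * (t1 - h)))
    vals <- c(vals, toe_z[mid])
  }
  if (!length(vals)) 0 else median(vals)
}

#' Summarize a subject's gait parameters by side
#'
#' Produces the per-parameter layout used for cohort features: mean and
#' intra-subject SD (sample SD, n-1 denominator) per side plus pooled over
#' both sides. Step metrics are stratified by leading foot; MFC by swing
#' foot. Subjects with fewer than `min_steps` total steps are flagged as
#' not included (the cohort inclusion rule is a minimum of 30 complete
#' step cycles).
#'
#' @param step_records from [compute_step_metrics()].
#' @param swing_records from [compute_mfc()].
#' @param min_steps inclusion threshold on total step count (default 30).
#' @param subject_id identifier carried into the summary.
#' @return a `subject_gait_summary`: list with a `parameters` data.frame
#'   (`parameter, mean_L, sd_L, mean_R, sd_R, mean_pooled, sd_pooled`),
#'   step/swing counts per side, and an `included` flag.
#' @export
summarize_subject <- function(step_records, swing_records, min_steps = 30,
                              subject_id = NA_character_) {
  side_vals <- function(param) {
    if (param == "mfc")
      list(L = swing_records$mfc_cm[swing_records$foot == "L"],
           R = swing_records$mfc_cm[swing_records$foot == "R"])
    else
      list(L = step_records[[param]][step_records$leading_foot == "L"],
           R = step_records[[param]][step_records$leading_foot == "R"])
  }
  rows <- lapply(GAIT_PARAMETERS, function(p) {
    v <- side_vals(p)
    if (!length(v$L) || !length(v$R))
      stop_gaitsym(sprintf(
        "no %s records on side %s: symmetry features undefined",
        p, if (!length(v$L)) "L" else "R"), "gaitsym_side_missing_error")
    pooled <- c(v$L, v$R)
    data.frame(parameter = p,
               mean_L = mean(v$L), sd_L = if (length(v$L) > 1) sd(v$L) else 0,
               mean_R = mean(v$R), sd_R = if (length(v$R) > 1) sd(v$R) else 0,
               mean_pooled = mean(pooled),
               sd_pooled = if (length(pooled) > 1) sd(pooled) else 0)
  })
  n_L <- sum(step_records$leading_foot == "L")
  n_R <- sum(step_records$leading_foot == "R")
  structure(list(
    subject_id = subject_id,
    parameters = do.call(rbind, rows),
    n_steps_L = n_L, n_steps_R = n_R,
    n_swings_L = sum(swing_records$foot == "L"),
    n_swings_R = sum(swing_records$foot == "R"),
    min_steps = min_steps,
    included = (n_L + n_R) >= min_steps),
    class = "subject_gait_summary")
}

#' @export
print.subject_gait_summary <- function(x, ...) {
  cat(sprintf("<subject_gait_summary> %s: %d L + %d R steps%s\n",
              x$subject_id, x$n_steps_L, x$n_steps_R,
              if (x$included) "" else sprintf(" (below min_steps = %d, not included)", x$min_steps)))
  print(x$parameters, row.names = FALSE, digits = 4)
  invisible(x)
}
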