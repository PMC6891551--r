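# Kinematic gait event detection from heel and toe trajectories.
#
# Heel contact: local minimum of the filtered heel vertical position whose
# mean vertical velocity over the preceding 50 ms is clearly negative
# (final descent) and whose height lies within 15 mm of the trial's
# 5th-percentile heel height (near the floor). A 0.4 s refractory interval
# (max cadence ~150 steps/min) suppresses duplicate minima, keeping the
# lowest candidate.
#
# Toe off: within each heel-contact-to-heel-contact cycle of a foot, the
# last upward zero crossing (<= 0 to > 0) of the filtered toe vertical
# velocity before the toe first rises more than 5 mm above its stance
# height (the swing lift-off), searched after the toe has settled from the
# previous landing.

#' Detect heel-contact and toe-off events
#'
#' @param trial a [trial_trajectories()] object (filtered with
#'   [preprocess_trial()]; unfiltered trials are filtered internally with
#'   `spec`).
#' @param spec [filter_spec()] used if the trial is not yet filtered.
#' @param refractory_s minimum spacing between same-type events (s).
#' @param height_tol_m heel contacts must lie within this height of the
#'   5th-percentile heel height (m).
#' @param vel_thresh_ms mean heel vertical velocity over the preceding
#'   `vel_window_s` must be below this (m/s) for a heel contact.
#' @param vel_window_s window for the pre-contact velocity gate (s).
#' @param rise_thresh_m toe lift threshold above stance height defining the
#'   end of the toe-off search window (m).
#' @param edge_trim_s events closer than this to the trial edges are
#'   discarded (gait initiation/termination are not steady-state).
#'
#' @return a `gait_events` object: `list(L = list(heel_contacts, toe_offs),
#'   R = ..., fs = )` with 1-based frame indices.
#' @export
detect_events <- function(trial, spec = filter_spec(fs = trial$fs),
                          refractory_s = 0.4, height_tol_m = 0.015,
                          vel_thresh_ms = -0.03, vel_window_s = 0.05,
                          rise_thresh_m = 0.005, edge_trim_s = 0.2) {
  trial <- ensure_filtered(trial, spec)
  fs <- trial$fs
  out <- list()
  for (side in c("L", "R")) {
    heel_z <- trial$positions[[paste0(side, "_HEEL")]][, "z"]
    toe_z <- trial$positions[[paste0(side, "_TOE")]][, "z"]
    hc <- detect_heel_contacts(heel_z, fs, refractory_s, height_tol_m,
                               vel_thresh_ms, vel_window_s, edge_trim_s)
    if (length(hc) < 2)
      stop_gaitsym(sprintf(
        "fewer than 2 heel contacts detected on side %s (stationary or corrupt markers?)",
        side), "gaitsym_insufficient_events_error")
    to <- detect_toe_offs(toe_z, hc, fs, rise_thresh_m)
    out[[side]] <- list(heel_contacts = hc, toe_offs = to)
  }
  out$fs <- fs
  structure(out, class = "gait_events")
}

detect_heel_contacts <- function(heel_z, fs, refractory_s, height_tol_m,
                                 vel_thresh_ms, vel_window_s, edge_trim_s) {
  heel_v <- derivative(heel_z, fs)
  cand <- local_minima(heel_z)
  if (!length(cand)) return(integer(0))
  w <- max(1L, round(vel_window_s * fs))
  pre_vel <- rollmean_trailing(heel_v, w)[cand]
  floor_ref <- quantile(heel_z, 0.05, names = FALSE)
  cand <- cand[pre_vel < vel_thresh_ms & heel_z[cand] < floor_ref + height_tol_m]
  if (!length(cand)) return(integer(0))
  # refractory pruning: accept lowest-first, then enforce spacing
  keep <- integer(0)
  for (i in cand[order(heel_z[cand])])
    if (!length(keep) || all(abs(keep - i) >= refractory_s * fs))
      keep <- c(keep, i)
  keep <- sort(keep)
  trim <- edge_trim_s * fs
  keep[keep > trim & keep <= length(heel_z) - trim]
}

detect_toe_offs <- function(toe_z, heel_contacts, fs, rise_thresh_m) {
  toe_v <- derivative(toe_z, fs)
  tos <- integer(0)
  for (k in seq_len(length(heel_contacts) - 1)) {
    a <- heel_contacts[k]
    b <- heel_contacts[k + 1]
    n <- b - a
    stance_ref <- median(toe_z[(a + round(0.1 * n)):(a + round(0.4 * n))])
    seg <- a:b
    settled <- seg[which(toe_z[seg] <= stance_ref + rise_thresh_m)[1]]
    if (is.na(settled)) next
    rest <- seg[seg > settled]
    exceed <- rest[which(toe_z[rest] > stance_ref + rise_thresh_m)[1]]
    if (is.na(exceed)) next
    vseg <- toe_v[a:exceed]
    cross <- which(vseg[-length(vseg)] <= 0 & vseg[-1] > 0)
    if (!length(cross)) next
    tos <- c(tos, a + cross[length(cross)] - 1L)
  }
  tos
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> @ %g Hz  L: %d HC / %d TO   R: %d HC / %d TO\n",
              x$fs, length(x$L$heel_contacts), length(x$L$toe_offs),
              length(x$R$heel_contacts), length(x$R$toe_offs)))
  invisible(x)
}

#' Assemble alternating step intervals from gait events
#'
#' A step runs from one foot's heel contact (the trailing foot) to the
#' other foot's next heel contact (the leading foot); the associated
#' double-support interval ends at the trailing foot's subsequent toe off.
#' Heel-contact subsequences violating strict left/right alternation
#' (missed detections) are skipped with a warning, never silently patched.
#'
#' @param events a `gait_events` object.
#' @param fs sampling rate (defaults to the events' rate).
#' @return data.frame with columns `leading_foot`, `trail_heel_contact`,
#'   `lead_heel_contact`, `trail_toe_off` (frame indices).
#' @export
segment_steps <- function(events, fs = events$fs) {
  foot <- c(rep("L", length(events$L$heel_contacts)),
            rep("R", length(events$R$heel_contacts)))
  frame <- c(events$L$heel_contacts, events$R$heel_contacts)
  o <- order(frame)
  foot <- foot[o]; frame <- frame[o]
  n <- length(frame)
  lead_f <- character(0); trail_hc <- lead_hc <- trail_to <- integer(0)
  dropped <- 0L
  for (k in seq_len(n - 1)) {
    if (foot[k] == foot[k + 1]) {
      dropped <- dropped + 1L
      next
    }
    to_pool <- events[[foot[k]]]$toe_offs
    to <- to_pool[to_pool > frame[k + 1]]
    nxt <- frame[frame > frame[k + 1] & foot == foot[k]]
    if (length(nxt)) to <- to[to < nxt[1]]
    if (!length(to)) next
    lead_f <- c(lead_f, foot[k + 1])
    trail_hc <- c(trail_hc, frame[k])
    lead_hc <- c(lead_hc, frame[k + 1])
    trail_to <- c(trail_to, to[1])
  }
  if (dropped > 0)
    warn_gaitsym(sprintf(
      "%d step(s) skipped: consecutive same-foot heel contacts (missed event?)",
      dropped), "gaitsym_alternation_warning")
  if (!length(lead_f))
    stop_gaitsym("no valid step intervals", "gaitsym_no_steps_error")
  out <- data.frame(leading_foot = lead_f, trail_heel_contact = trail_hc,
                    lead_heel_contact = lead_hc, trail_toe_off = trail_to)
  stopifnot(all(out$trail_heel_contact < out$lead_heel_contact),
            all(out$lead_heel_contact < out$trail_toe_off))
  out
}
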