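#' Construct a four-marker walking trial
#'
#' A `trial_trajectories` object holds time-synchronized 3D positions of the
#' left/right heel and toe markers for one straight overground walking pass,
#' in meters, in the lab frame (x anterior, y to the participant's left,
#' z vertical up, walking surface near z = 0).
#'
#' @param positions named list with elements `L_HEEL`, `R_HEEL`, `L_TOE`,
#'   `R_TOE`, each an `n x 3` numeric matrix with columns `x`, `y`, `z`
#'   (meters).
#' @param fs sampling rate in Hz.
#' @param subject_id,trial_id identifier strings.
#' @param validate if `TRUE` (default), reject trials violating the type
#'   invariants (all markers present with equal frame counts, positive
#'   sampling rate, at least 2 s of data, no non-finite values).
#'
#' @return a `trial_trajectories` object.
#' @export
trial_trajectories <- function(positions, fs = 100, subject_id = "S1",
                               trial_id = "T1", validate = TRUE) {
  obj <- structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         fs = as.numeric(fs),
         frames = if (length(positions)) nrow(positions[[1]]) else 0L,
         positions = lapply(positions, function(m) {
           m <- as.matrix(m)
           colnames(m) <- c("x", "y", "z")
           m
         })),
    class = "trial_trajectories")
  if (validate) {
    issues <- validate_trial(obj)
    if (length(issues))
      stop_gaitsym(paste0("invalid trial: ", paste(issues, collapse = "; ")),
                   "gaitsym_format_error")
  }
  obj
}

#' Check a trial against the trajectory invariants
#'
#' Reports, rather than errors: returns a character vector of issue
#' descriptions, empty when the trial is valid. Checked invariants: all four
#' markers present with identical frame counts; `fs > 0`; at least
#' `2 s * fs` frames; no non-finite values (marker gaps must be interpolated
#' on load, see [read_marker_table()]).
#'
#' @param trial a `trial_trajectories` object.
#' @return character vector of issues (empty if valid).
#' @export
validate_trial <- function(trial) {
  issues <- character(0)
  missing <- setdiff(MARKER_NAMES, names(trial$positions))
  if (length(missing))
    issues <- c(issues, paste0("missing marker ", missing))
  if (!is.numeric(trial$fs) || length(trial$fs) != 1 ||
      !is.finite(trial$fs) || trial$fs <= 0)
    issues <- c(issues, "invalid sampling rate")
  present <- intersect(MARKER_NAMES, names(trial$positions))
  nf <- vapply(trial$positions[present], nrow, integer(1))
  if (length(nf) && length(unique(nf)) > 1)
    issues <- c(issues, "markers have differing frame counts")
  for (m in present) {
    bad <- which(!is.finite(trial$positions[[m]]))
    if (length(bad)) {
      rows <- sort(unique((bad - 1) %% nrow(trial$positions[[m]]) + 1))
      issues <- c(issues, sprintf(
        "%s: non-finite values in frames %d-%d (gap too long or unfilled)",
        m, min(rows), max(rows)))
    }
  }
  if (length(nf) && is.finite(trial$fs) && trial$fs > 0 &&
      min(nf) < 2 * trial$fs)
    issues <- c(issues, sprintf(
      "trial too short: %d frames < 2 s at %g Hz", min(nf), trial$fs))
  issues
}

#' @export
print.trial_trajectories <- function(x, ...) {
  cat(sprintf("<trial_trajectories> subject %s trial %s: %d frames @ %g Hz (%.1f s)\n",
              x$subject_id, x$trial_id, x$frames, x$fs, x$frames / x$fs))
  if (isTRUE(attr(x, "filtered"))) cat("  low-pass filtered\n")
  invisible(x)
}

# Net anterior displacement of the mean heel trajectory; used to normalize
# walking direction to +x on load.
net_progression <- function(trial) {
  hx <- (trial$positions$L_HEEL[, "x"] + trial$positions$R_HEEL[, "x"]) / 2
  hx[length(hx)] - hx[1]
}

# Rotate a trial 180 degrees about the vertical axis (x -> -x, y -> -y).
rotate_180 <- function(trial) {
  trial$positions <- lapply(trial$positions, function(m) {
    m[, "x"] <- -m[, "x"]
    m[, "y"] <- -m[, "y"]
    m
  })
  trial
}
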