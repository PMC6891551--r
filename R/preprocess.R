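#' Low-pass filter specification
#'
#' Describes the zero-phase Butterworth smoothing applied to marker
#' trajectories before any kinematic analysis. The stated `order` is the
#' effective order of the forward-backward (zero-phase) application: the
#' default `order = 4` is realized as a second-order Butterworth run
#' forward then backward, the standard practice in gait analysis. No
#' cutoff-frequency correction is applied for the dual pass, so the
#' magnitude response at `cutoff_hz` is exactly 1/2.
#'
#' @param cutoff_hz design cutoff frequency in Hz (default 6, the
#'   conventional choice for foot marker data).
#' @param order effective filter order; must be even and >= 2.
#' @param fs sampling rate in Hz.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(cutoff_hz = 6, order = 4, fs = 100) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop_gaitsym("cutoff_hz must satisfy 0 < cutoff_hz < fs/2",
                 "gaitsym_spec_error")
  if (order %% 2 != 0 || order < 2)
    stop_gaitsym("order must be even and >= 2", "gaitsym_spec_error")
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order), fs = fs),
            class = "filter_spec")
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a Butterworth filter of order `spec$order / 2` forward and
#' backward (zero phase lag, DC gain 1). The series is extended by
#' reflection before filtering and trimmed afterwards to suppress endpoint
#' transients on short walkway passes; the reflection length is six
#' filter time constants (`6 * fs / cutoff_hz` samples, capped at the
#' series length), long enough for startup transients to decay below
#' 1e-9 relative amplitude.
#'
#' @param series numeric vector.
#' @param spec a [filter_spec()].
#' @return filtered series, same length.
#' @export
lowpass_filter <- function(series, spec = filter_spec()) {
  n <- length(series)
  if (n < 3 * spec$order + 1)
    stop_gaitsym(sprintf("series too short to filter: %d < %d frames",
                         n, 3 * spec$order + 1),
                 "gaitsym_filter_length_error")
  bf <- signal::butter(spec$order / 2, spec$cutoff_hz / (spec$fs / 2), "low")
  L <- min(n - 1, 6 * ceiling(spec$fs / spec$cutoff_hz))
  pad_head <- 2 * series[1] - series[(L + 1):2]
  pad_tail <- 2 * series[n] - series[(n - 1):(n - L)]
  x <- c(pad_head, series, pad_tail)
  y <- as.numeric(signal::filter(bf, x))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(L + 1):(L + n)]
}

#' Numerical differentiation of a marker coordinate
#'
#' Central differences on interior frames, one-sided at the endpoints;
#' `order = 1` gives velocity (m/s for a position input), `order = 2`
#' acceleration via the central second difference.
#'
#' @param series numeric vector (typically an already-filtered coordinate).
#' @param fs sampling rate in Hz.
#' @param order 1 (velocity) or 2 (acceleration).
#' @return derivative series, same length as the input.
#' @export
derivative <- function(series, fs, order = 1) {
  n <- length(series)
  if (n < 3)
    stop_gaitsym("series too short to differentiate (need >= 3 frames)",
                 "gaitsym_derivative_length_error")
  if (!order %in% c(1, 2))
    stop_gaitsym("order must be 1 or 2", "gaitsym_spec_error")
  v <- numeric(n)
  if (order == 1) {
    v[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) * fs / 2
    v[1] <- (series[2] - series[1]) * fs
    v[n] <- (series[n] - series[n - 1]) * fs
  } else {
    v[2:(n - 1)] <- (series[3:n] - 2 * series[2:(n - 1)] + series[1:(n - 2)]) * fs^2
    v[1] <- v[2]
    v[n] <- v[n - 1]
  }
  v
}

#' Filter all marker coordinates of a trial
#'
#' Smooths every coordinate of every marker with [lowpass_filter()] and
#' marks the trial as filtered; downstream operations that require a
#' filtered trial apply this automatically when needed.
#'
#' @param trial a [trial_trajectories()] object.
#' @param spec a [filter_spec()]; its `fs` is overridden by the trial's.
#' @return the filtered trial.
#' @export
preprocess_trial <- function(trial, spec = filter_spec()) {
  spec$fs <- trial$fs
  trial$positions <- lapply(trial$positions, function(m) {
    for (j in seq_len(ncol(m))) m[, j] <- lowpass_filter(m[, j], spec)
    m
  })
  attr(trial, "filtered") <- TRUE
  trial
}

ensure_filtered <- function(trial, spec = filter_spec()) {
  if (isTRUE(attr(trial, "filtered"))) trial else preprocess_trial(trial, spec)
}
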