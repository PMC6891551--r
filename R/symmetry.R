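#' Left-right Symmetry Index
#'
#' `SI = |R - L| / ((R + L) / 2) * 100`, the absolute left-right difference
#' normalized by the inter-limb mean, in percent. 0 means perfect symmetry;
#' 200 is the boundary where one side's value is zero. Symmetric in its
#' arguments and invariant to a common positive rescaling of both sides.
#'
#' @param r_value,l_value nonnegative quantities in the same units
#'   (vectorized).
#' @return symmetry index in percent.
#' @export
symmetry_index <- function(r_value, l_value) {
  if (any(r_value < 0 | l_value < 0))
    stop_gaitsym("symmetry_index requires nonnegative inputs",
                 "gaitsym_spec_error")
  if (any(r_value + l_value == 0))
    stop_gaitsym("symmetry index undefined: R + L = 0",
                 "gaitsym_si_undefined_error")
  abs(r_value - l_value) / ((r_value + l_value) / 2) * 100
}

#' Symmetry Index feature set for one subject
#'
#' Applies [symmetry_index()] to both the mean and the intra-subject SD of
#' each of the four gait parameters, yielding 8 features (`si_mean_*`,
#' `si_sd_*`).
#'
#' @param summary a `subject_gait_summary` from [summarize_subject()].
#' @return named numeric vector of 8 SI values (percent).
#' @export
si_features <- function(summary) {
  p <- summary$parameters
  if (any(!is.finite(c(p$mean_L, p$mean_R, p$sd_L, p$sd_R))))
    stop_gaitsym("summary has missing side values", "gaitsym_side_missing_error")
  out <- c(symmetry_index(p$mean_R, p$mean_L),
           symmetry_index(p$sd_R, p$sd_L))
  names(out) <- c(paste0("si_mean_", p$parameter), paste0("si_sd_", p$parameter))
  out
}

#' Score a GHQ-12 response
#'
#' Bimodal (0-0-1-1) scoring: each of the 12 items, answered on a 4-point
#' scale coded 0-3, contributes 1 point when answered on the "agree" side
#' (codes 2 or 3) and 0 otherwise, for a total of 0-12. Higher totals
#' indicate worse general mental health.
#'
#' @param items either an integer vector of 12 item codes in `0:3`, or a
#'   `ghq_responses` data.frame from [read_ghq_csv()].
#' @return for a vector: the integer total; for a data.frame: a data.frame
#'   `subject_id, ghq_total`.
#' @export
score_ghq12 <- function(items) {
  if (is.data.frame(items)) {
    cols <- grep("^item", names(items), value = TRUE)
    totals <- apply(as.matrix(items[, cols]), 1, score_ghq12)
    return(data.frame(subject_id = as.character(items$subject_id),
                      ghq_total = totals))
  }
  items <- as.vector(items)
  if (length(items) != 12)
    stop_gaitsym(sprintf("expected 12 items, got %d", length(items)),
                 "gaitsym_response_coding_error")
  if (!all(items %in% 0:3))
    stop_gaitsym("item codes must be integers in 0..3",
                 "gaitsym_response_coding_error")
  sum(items >= 2)
}
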