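# End-to-end orchestration: simulate or load trials, extract the
# per-subject feature table, score GHQ-12, and run the cohort statistics,
# with a manifest recording inclusion/exclusion and warning counts.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default.
#' Serializable to/from YAML for the command-line interface.
#'
#' @param filter_cutoff_hz,filter_order low-pass filter design
#'   ([filter_spec()]).
#' @param refractory_s,height_tol_m,vel_thresh_ms,vel_window_s,rise_thresh_m,edge_trim_s
#'   event-detection thresholds ([detect_events()]).
#' @param mfc_window swing fraction searched for clearance minima.
#' @param ground_ref `"midstance"` or `"absolute"` ([compute_mfc()]).
#' @param min_steps inclusion threshold on total steps per subject.
#' @param predictors regression predictor set; `NULL` = 16 features + age.
#' @param seed base RNG seed.
#' @param out_dir output directory for [run_pipeline()].
#' @return a `pipeline_config` object (a validated list).
#' @export
pipeline_config <- function(filter_cutoff_hz = 6, filter_order = 4,
                            refractory_s = 0.4, height_tol_m = 0.015,
                            vel_thresh_ms = -0.03, vel_window_s = 0.05,
                            rise_thresh_m = 0.005, edge_trim_s = 0.2,
                            mfc_window = c(0.2, 0.8),
                            ground_ref = c("midstance", "absolute"),
                            min_steps = 30, predictors = NULL,
                            seed = 1, out_dir = NULL) {
  ground_ref <- match.arg(ground_ref)
  cfg <- list(filter_cutoff_hz = filter_cutoff_hz, filter_order = filter_order,
              refractory_s = refractory_s, height_tol_m = height_tol_m,
              vel_thresh_ms = vel_thresh_ms, vel_window_s = vel_window_s,
              rise_thresh_m = rise_thresh_m, edge_trim_s = edge_trim_s,
              mfc_window = mfc_window, ground_ref = ground_ref,
              min_steps = min_steps, predictors = predictors,
              seed = seed, out_dir = out_dir)
  stopifnot(filter_cutoff_hz > 0, filter_order >= 2,
            refractory_s > 0, length(mfc_window) == 2,
            mfc_window[1] >= 0, mfc_window[2] <= 1,
            mfc_window[1] < mfc_window[2], min_steps >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_gaitsym(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 "gaitsym_spec_error")
  do.call(pipeline_config, vals)
}

#' Extract the per-subject gait feature table
#'
#' Runs filtering, event detection, step segmentation, spatiotemporal
#' parameter extraction, clearance extraction, per-side summaries and
#' Symmetry Index features for every subject's trial, producing one row
#' per subject with the 16 gait feature columns. Subjects whose trial
#' fails a pipeline stage are excluded with the reason recorded in the
#' `exclusions` attribute rather than aborting the whole cohort.
#'
#' @param trials a named list of [trial_trajectories()] (names are subject
#'   ids), or a `synthetic_cohort` from [simulate_cohort()].
#' @param config a [pipeline_config()].
#' @return data.frame: `subject_id, n_steps_L, n_steps_R, included`, then
#'   the 16 features; attributes `exclusions` (data.frame) and `warnings`
#'   (named counts).
#' @export
extract_features <- function(trials, config = pipeline_config()) {
  if (inherits(trials, "synthetic_cohort")) trials <- trials$trials
  fspec_for <- function(trial)
    filter_spec(config$filter_cutoff_hz, config$filter_order, trial$fs)
  rows <- list()
  excl <- list()
  warn_counts <- c()
  for (id in names(trials)) {
    trial <- trials[[id]]
    res <- withCallingHandlers(
      tryCatch(subject_features(trial, config, fspec_for(trial)),
               gaitsym_error = function(e) e),
      gaitsym_warning = function(w) {
        cls <- class(w)[1]
        warn_counts[cls] <<- (if (is.na(warn_counts[cls])) 0 else warn_counts[cls]) + 1
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "gaitsym_error")) {
      excl[[length(excl) + 1]] <- data.frame(
        subject_id = id, reason = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1]] <- cbind(subject_id = id, res)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0))
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(0), reason = character(0))
  attr(out, "warnings") <- warn_counts
  out
}

subject_features <- function(trial, config, fspec) {
  trial <- ensure_filtered(trial, fspec)
  events <- detect_events(trial, fspec,
                          refractory_s = config$refractory_s,
                          height_tol_m = config$height_tol_m,
                          vel_thresh_ms = config$vel_thresh_ms,
                          vel_window_s = config$vel_window_s,
                          rise_thresh_m = config$rise_thresh_m,
                          edge_trim_s = config$edge_trim_s)
  steps <- segment_steps(events)
  step_rec <- compute_step_metrics(trial, steps)
  swing_rec <- compute_mfc(trial, events, ground_ref = config$ground_ref,
                           window = config$mfc_window)
  summ <- summarize_subject(step_rec, swing_rec,
                            min_steps = config$min_steps,
                            subject_id = trial$subject_id)
  si <- si_features(summ)
  p <- summ$parameters
  vals <- c()
  for (k in seq_len(nrow(p))) {
    pn <- p$parameter[k]
    vals[paste0(pn, "_mean")] <- p$mean_pooled[k]
    vals[paste0(pn, "_si_mean")] <- si[[paste0("si_mean_", pn)]]
    vals[paste0(pn, "_sd")] <- p$sd_pooled[k]
    vals[paste0(pn, "_si_sd")] <- si[[paste0("si_sd_", pn)]]
  }
  cbind(data.frame(n_steps_L = summ$n_steps_L, n_steps_R = summ$n_steps_R,
                   included = summ$included),
        as.data.frame(as.list(vals)))
}

#' Cohort association analysis
#'
#' Merges the feature table with GHQ-12 totals (and optional covariates),
#' drops subjects failing the inclusion rule or with missing cells
#' (listwise, with reasons), and computes the correlation table and the
#' multiple regression.
#'
#' @param features output of [extract_features()].
#' @param ghq `ghq_responses` item table, or a data.frame with
#'   `subject_id, ghq_total`.
#' @param subjects optional data.frame of covariates keyed by
#'   `subject_id` (e.g. `age`, `sex`).
#' @param config a [pipeline_config()] (for the predictor set).
#' @return list: `table` (merged analysis table), `correlations`,
#'   `regression`, `excluded` (ids + reasons).
#' @export
analyze_cohort <- function(features, ghq, subjects = NULL,
                           config = pipeline_config()) {
  totals <- if ("ghq_total" %in% names(ghq)) ghq[, c("subject_id", "ghq_total")]
            else score_ghq12(ghq)
  tab <- merge(features, totals, by = "subject_id")
  if (!is.null(subjects)) tab <- merge(tab, subjects, by = "subject_id")
  excluded <- attr(features, "exclusions")
  not_incl <- tab$subject_id[!tab$included]
  if (length(not_incl))
    excluded <- rbind(excluded, data.frame(
      subject_id = not_incl,
      reason = sprintf("fewer than %d steps", config$min_steps)))
  tab <- tab[tab$included, ]
  cors <- correlation_table(tab)
  reg <- fit_ols(tab, predictors = config$predictors)
  list(table = tab, correlations = cors, regression = reg,
       excluded = excluded)
}

#' Run the full pipeline and write a report bundle
#'
#' Either simulates a cohort (when `cohort` is given) or reads marker and
#' GHQ files from disk, extracts features, runs the cohort statistics,
#' and writes `features.csv`, `correlations.csv`, `regression.json` and
#' `manifest.json` into `config$out_dir`. Deterministic for a fixed
#' config and seed.
#'
#' @param config a [pipeline_config()] with `out_dir` set.
#' @param cohort a [cohort_spec()] to simulate, or `NULL` to read inputs.
#' @param marker_paths named character vector of marker file paths
#'   (names = subject ids) when not simulating.
#' @param ghq_path GHQ-12 CSV path when not simulating.
#' @return the [analyze_cohort()] bundle, invisibly, with `features`
#'   attached.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         marker_paths = NULL, ghq_path = NULL) {
  if (is.null(config$out_dir))
    stop_gaitsym("config$out_dir must be set", "gaitsym_spec_error")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort)) {
    sim <- simulate_cohort(cohort, seed = config$seed)
    trials <- sim$trials
    ghq <- sim$ghq
    subjects <- sim$subjects
  } else {
    if (is.null(marker_paths) || is.null(ghq_path))
      stop_gaitsym("need marker_paths and ghq_path when not simulating",
                   "gaitsym_spec_error")
    trials <- lapply(marker_paths, read_marker_table)
    names(trials) <- names(marker_paths)
    ghq <- read_ghq_csv(ghq_path)
    subjects <- NULL
  }
  features <- extract_features(trials, config)
  bundle <- analyze_cohort(features, ghq, subjects, config)
  out <- config$out_dir
  write.csv(features, file.path(out, "features.csv"), row.names = FALSE)
  write.csv(bundle$correlations, file.path(out, "correlations.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    bundle$regression[c("r", "r_squared", "F", "df1", "df2", "p", "n")],
    file.path(out, "regression.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    n_subjects = length(trials),
    n_included = nrow(bundle$table),
    excluded = bundle$excluded,
    warning_counts = as.list(attr(features, "warnings")),
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))])
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(cohort)) {
    truth_path <- file.path(out, "ground_truth.json")
    jsonlite::write_json(sim$truth$si_true, truth_path, digits = NA)
  }
  bundle$features <- features
  invisible(bundle)
}
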