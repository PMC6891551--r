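# File formats:
#  * TRC: OpenSim-style tab-separated, header carries DataRate / NumFrames /
#    Units; positions conventionally in mm.
#  * csv_wide: one metadata line "# fs=100,units=m", then a CSV table
#    "frame,LHEEL_x,LHEEL_y,LHEEL_z,RHEEL_x,...".
# Marker names are matched after stripping non-alphanumerics, so "L_HEEL"
# and "LHEEL" are equivalent.

MAX_GAP_FRAMES <- 10L  # linear interpolation limit for marker occlusions

normalize_marker <- function(x) gsub("[^A-Za-z0-9]", "", toupper(x))

match_markers <- function(found) {
  key <- normalize_marker(MARKER_NAMES)
  idx <- match(key, normalize_marker(found))
  names(idx) <- MARKER_NAMES
  idx
}

# Fill occlusion gaps (NA runs) by linear interpolation up to
# MAX_GAP_FRAMES consecutive frames; longer gaps reject the trial.
fill_gaps <- function(m, marker) {
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    x[!is.finite(x)] <- NA_real_
    if (!anyNA(x)) { m[, j] <- x; next }
    r <- rle(is.na(x))
    if (any(r$values & r$lengths > MAX_GAP_FRAMES)) {
      at <- cumsum(r$lengths)[which(r$values & r$lengths > MAX_GAP_FRAMES)[1]]
      stop_gaitsym(sprintf(
        "%s: gap of more than %d frames ending at frame %d",
        marker, MAX_GAP_FRAMES, at), "gaitsym_gap_too_long_error")
    }
    m[, j] <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
  }
  m
}

#' Read a four-marker trajectory file
#'
#' Reads a TRC or wide-CSV marker file, converts positions to meters,
#' linearly interpolates occlusion gaps up to 10 consecutive frames, and
#' normalizes walking direction so that the pass progresses in +x (a trial
#' walked toward -x is rotated 180 degrees about the vertical axis).
#'
#' @param path file path.
#' @param format `"trc"` or `"csv_wide"`; default inferred from the file
#'   extension.
#' @param subject_id,trial_id identifiers; default to the file name.
#' @return a validated [trial_trajectories()] object.
#' @export
read_marker_table <- function(path, format = c("auto", "trc", "csv_wide"),
                              subject_id = NULL, trial_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_gaitsym(paste0("file not found: ", path), "gaitsym_format_error")
  if (format == "auto")
    format <- if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv_wide"
  base <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(subject_id)) subject_id <- base
  if (is.null(trial_id)) trial_id <- base
  parsed <- if (format == "trc") parse_trc(path) else parse_csv_wide(path)
  pos <- list()
  for (m in MARKER_NAMES)
    pos[[m]] <- fill_gaps(parsed$positions[[m]], m)
  trial <- trial_trajectories(pos, fs = parsed$fs, subject_id = subject_id,
                              trial_id = trial_id)
  if (net_progression(trial) < 0) trial <- rotate_180(trial)
  trial
}

parse_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6 || !grepl("^PathFileType", lines[1]))
    stop_gaitsym("not a TRC file (missing PathFileType header)",
                 "gaitsym_format_error")
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- setNames(as.list(hdr_vals), hdr_names)
  fs <- as.numeric(hdr[["DataRate"]])
  units <- hdr[["Units"]]
  if (is.null(units) || !(tolower(units) %in% c("mm", "m")))
    stop_gaitsym(paste0("unknown units in TRC header: ",
                        if (is.null(units)) "<missing>" else units),
                 "gaitsym_format_error")
  scale <- if (tolower(units) == "mm") 1e-3 else 1
  marker_row <- strsplit(lines[4], "\t")[[1]]
  markers <- marker_row[marker_row != "" &
                          !(marker_row %in% c("Frame#", "Time"))]
  idx <- match_markers(markers)
  if (anyNA(idx))
    stop_gaitsym(paste0("missing marker(s): ",
                        paste(names(idx)[is.na(idx)], collapse = ", ")),
                 "gaitsym_missing_marker_error")
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- strsplit(data_lines, "\t")
  ncol_expect <- 2 + 3 * length(markers)
  dat <- matrix(NA_real_, nrow = length(rows), ncol = ncol_expect)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    dat[i, seq_len(min(length(v), ncol_expect))] <-
      v[seq_len(min(length(v), ncol_expect))]
  }
  positions <- lapply(idx, function(k) {
    cols <- 2 + (k - 1) * 3 + 1:3
    dat[, cols, drop = FALSE] * scale
  })
  list(fs = fs, positions = positions)
}

parse_csv_wide <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (!grepl("fs\\s*=", first))
    stop_gaitsym("csv_wide file must start with a metadata line like '# fs=100,units=m'",
                 "gaitsym_format_error")
  meta <- gsub("^#\\s*", "", first)
  kv <- strsplit(strsplit(meta, ",")[[1]], "=")
  meta <- setNames(vapply(kv, function(p) trimws(p[2]), character(1)),
                   vapply(kv, function(p) trimws(tolower(p[1])), character(1)))
  fs <- as.numeric(meta[["fs"]])
  units <- meta[["units"]]
  if (is.na(units) || !(tolower(units) %in% c("mm", "m")))
    stop_gaitsym(paste0("unknown or missing units in metadata line"),
                 "gaitsym_format_error")
  scale <- if (tolower(units) == "mm") 1e-3 else 1
  tab <- read.csv(path, skip = 1, check.names = FALSE)
  cn <- names(tab)
  positions <- list()
  # match columns by normalized marker name + axis suffix
  norm_cn <- paste0(normalize_marker(sub("_[xyzXYZ]$", "", cn)), "_",
                    tolower(sub("^.*_([xyzXYZ])$", "\\1", cn)))
  for (m in MARKER_NAMES) {
    want <- paste0(normalize_marker(m), "_", c("x", "y", "z"))
    got <- match(want, norm_cn)
    if (anyNA(got))
      stop_gaitsym(paste0("missing marker: ", m),
                   "gaitsym_missing_marker_error")
    positions[[m]] <- as.matrix(tab[, got]) * scale
  }
  list(fs = fs, positions = positions)
}

#' Write a four-marker trajectory file
#'
#' Inverse of [read_marker_table()]: round-trips within numeric precision.
#' TRC files are written in mm (the format's convention); wide CSV in
#' meters with a `# fs=...,units=m` metadata line.
#'
#' @param trial a valid [trial_trajectories()] object.
#' @param path output path.
#' @param format `"trc"` or `"csv_wide"`.
#' @export
write_marker_table <- function(trial, path, format = c("trc", "csv_wide")) {
  format <- match.arg(format)
  issues <- validate_trial(trial)
  if (length(issues))
    stop_gaitsym(paste0("refusing to write invalid trial: ",
                        paste(issues, collapse = "; ")),
                 "gaitsym_format_error")
  if (format == "trc") write_trc(trial, path) else write_csv_wide(trial, path)
  invisible(path)
}

write_trc <- function(trial, path) {
  n <- trial$frames
  fs <- trial$fs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", fs, fs, n, length(MARKER_NAMES), fs, n),
    paste(c("Frame#", "Time",
            unlist(lapply(MARKER_NAMES, function(m) c(m, "", "")))),
          collapse = "\t"),
    paste(c("", "", unlist(lapply(seq_along(MARKER_NAMES), function(k)
      paste0(c("X", "Y", "Z"), k)))), collapse = "\t")
  ), con)
  mm <- do.call(cbind, lapply(trial$positions[MARKER_NAMES],
                              function(m) m * 1000))
  t <- (seq_len(n) - 1) / fs
  body <- cbind(seq_len(n), t, mm)
  writeLines(apply(body, 1, function(r)
    paste(formatC(r, format = "g", digits = 15), collapse = "\t")), con)
}

write_csv_wide <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g,units=m", trial$fs), con)
  tab <- data.frame(frame = seq_len(trial$frames))
  for (m in MARKER_NAMES)
    for (ax in c("x", "y", "z"))
      tab[[paste0(normalize_marker(m), "_", ax)]] <- trial$positions[[m]][, ax]
  write.csv(tab, con, row.names = FALSE, quote = FALSE)
}

#' Read GHQ-12 questionnaire responses
#'
#' Expects a CSV with columns `subject_id, item01, ..., item12`, each item
#' an integer code 0-3 (0-1 the "disagree" pole, 2-3 the "agree" pole;
#' item polarity reversal for positively worded questions is assumed to be
#' encoded upstream).
#'
#' @param path CSV path.
#' @return data.frame of class `ghq_responses`.
#' @export
read_ghq_csv <- function(path) {
  tab <- read.csv(path)
  items <- grep("^item", names(tab), value = TRUE)
  if (length(items) != 12 || !("subject_id" %in% names(tab)))
    stop_gaitsym("GHQ CSV must have columns subject_id, item01..item12",
                 "gaitsym_response_coding_error")
  vals <- as.matrix(tab[, items])
  if (!all(vals %in% 0:3))
    stop_gaitsym("GHQ item codes must be integers in 0..3",
                 "gaitsym_response_coding_error")
  tab$subject_id <- as.character(tab$subject_id)
  class(tab) <- c("ghq_responses", "data.frame")
  tab
}

#' Export detected gait events as a tidy CSV
#'
#' One row per event: `foot,event_type,frame,time_s`.
#'
#' @param events a `gait_events` object from [detect_events()].
#' @param path output CSV path.
#' @export
write_events_csv <- function(events, path) {
  rows <- do.call(rbind, lapply(c("L", "R"), function(f) {
    rbind(
      data.frame(foot = f, event_type = "heel_contact",
                 frame = events[[f]]$heel_contacts),
      data.frame(foot = f, event_type = "toe_off",
                 frame = events[[f]]$toe_offs))
  }))
  rows$time_s <- (rows$frame - 1) / events$fs
  rows <- rows[order(rows$frame), ]
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
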