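# CSV dialects: EMG and joint-angle time series, segment marks, ground
# truth, and the study manifest.

infer_fs <- function(time_s, expected = NULL, what = "time") {
  d <- diff(time_s)
  if (any(d <= 0)) abort_input(sprintf("non-monotone %s column", what))
  fs <- 1 / median(d)
  if (!is.null(expected) && abs(fs - expected) / expected > 0.001) {
    abort_input(sprintf(
      "sampling rate %.4g Hz differs from expected %.4g Hz by more than 0.1%%",
      fs, expected))
  }
  fs
}

#' Write / read the EMG CSV dialect
#'
#' Columns: `time_s`, then one column per muscle (microvolt).
#'
#' @param rec An `emg_recording`.
#' @param path File path.
#' @return `write_emg_csv`: the path, invisibly. `read_emg_csv`: an
#'   `emg_recording`; the sampling rate is inferred from the time column and,
#'   when `fs` is given, checked against it within 0.1%.
#' @export
write_emg_csv <- function(rec, path) {
  df <- data.frame(time_s = (seq_len(nrow(rec$samples)) - 1) / rec$fs,
                   rec$samples, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param fs Expected sampling rate (Hz), optional.
#' @param muscles Expected channel names, optional; a missing channel is a
#'   schema error naming the column.
#' @param meta Metadata list attached to the recording.
#' @export
read_emg_csv <- function(path, fs = NULL, muscles = NULL, meta = list()) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  df <- data.table::fread(path, data.table = FALSE)
  if (!"time_s" %in% names(df)) abort_input("missing `time_s` column")
  chan <- setdiff(names(df), "time_s")
  if (!is.null(muscles)) {
    missing <- setdiff(muscles, chan)
    if (length(missing)) {
      abort_input(sprintf("missing muscle column(s): %s",
                          paste(missing, collapse = ", ")))
    }
    chan <- muscles
  }
  fs_obs <- infer_fs(df$time_s, fs)
  new_emg_recording(as.matrix(df[, chan, drop = FALSE]),
                    fs = if (is.null(fs)) fs_obs else fs,
                    muscles = chan, meta = meta)
}

#' Write / read the joint-angle CSV dialect
#'
#' Columns: `time_s`, then one column per joint coordinate (degrees).
#'
#' @param rec A `motion_recording`.
#' @param path File path.
#' @export
write_mocap_csv <- function(rec, path) {
  df <- data.frame(time_s = (seq_len(nrow(rec$angles)) - 1) / rec$fs,
                   rec$angles, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_mocap_csv
#' @param fs Expected sampling rate (Hz), optional.
#' @param coordinates Required coordinate columns, optional.
#' @param meta Metadata list attached to the recording.
#' @export
read_mocap_csv <- function(path, fs = NULL, coordinates = NULL, meta = list()) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  df <- data.table::fread(path, data.table = FALSE)
  if (!"time_s" %in% names(df)) abort_input("missing `time_s` column")
  chan <- setdiff(names(df), "time_s")
  if (!is.null(coordinates)) {
    missing <- setdiff(coordinates, chan)
    if (length(missing)) {
      abort_input(sprintf("missing coordinate column(s): %s",
                          paste(missing, collapse = ", ")))
    }
    chan <- coordinates
  }
  fs_obs <- infer_fs(df$time_s, fs)
  new_motion_recording(as.matrix(df[, chan, drop = FALSE]),
                       fs = if (is.null(fs)) fs_obs else fs,
                       coordinates = chan, meta = meta)
}

#' Write / read segment marks CSV
#'
#' Columns: `exercise_id` (optional on read), `box`, `start_s`, `end_s`,
#' `flag`, plus `start_sample`/`end_sample` for refined marks.
#'
#' @param marks Marks data frame.
#' @param path File path.
#' @export
write_marks_csv <- function(marks, path) {
  data.table::fwrite(marks, path)
  invisible(path)
}

#' @rdname write_marks_csv
#' @export
read_marks_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  df <- data.table::fread(path, data.table = FALSE)
  check_marks(df)
  if (is.null(df$flag)) df$flag <- ""
  df$flag[is.na(df$flag)] <- ""
  df
}

write_ground_truth <- function(truth, path) {
  tg <- truth$targets
  at <- match(tg$box, truth$intervals$box)  # keep target row order
  tg$start_s <- truth$intervals$start_s[at]
  tg$end_s <- truth$intervals$end_s[at]
  tg$subject_factor <- truth$subject_factor
  data.table::fwrite(
    tg[, c("box", "start_s", "end_s", "muscle", "amplitude_uV",
           "realized_uV", "center_freq_hz", "subject_factor")], path)
  invisible(path)
}

read_ground_truth <- function(path) {
  tg <- data.table::fread(path, data.table = FALSE)
  structure(list(
    intervals = unique(tg[, c("box", "start_s", "end_s")]),
    targets = tg[, c("muscle", "box", "amplitude_uV", "center_freq_hz",
                     "realized_uV")],
    subject_factor = tg$subject_factor[1]), class = "emg_ground_truth")
}

#' Read a study manifest
#'
#' One row per exercise: `subject`, `condition`, `weight_kg`, `exercise_id`,
#' `emg_path`, `mocap_path`, `marks_path`. The (subject, condition, weight)
#' triples must be unique; paths are resolved relative to the manifest.
#'
#' @param path Manifest CSV path.
#' @return The manifest data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  mf <- data.table::fread(path, data.table = FALSE)
  need <- c("subject", "condition", "weight_kg", "exercise_id",
            "emg_path", "mocap_path", "marks_path")
  missing <- setdiff(need, names(mf))
  if (length(missing)) {
    abort_input(sprintf("manifest missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  key <- paste(mf$subject, mf$condition, mf$weight_kg)
  if (anyDuplicated(key)) {
    abort_input("duplicate (subject, condition, weight) triples in manifest")
  }
  base <- dirname(normalizePath(path))
  for (col in c("emg_path", "mocap_path", "marks_path", "truth_path")) {
    if (!is.null(mf[[col]])) {
      mf[[col]] <- ifelse(file.exists(mf[[col]]), mf[[col]],
                          file.path(base, basename(mf[[col]])))
    }
  }
  mf
}
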