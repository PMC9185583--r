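# Study-wide pipeline driver and its configuration.

#' Default pipeline configuration
#'
#' All analysis constants live here (never hard-coded downstream): the
#' 20--200 Hz order-10 zero-phase band-pass, 0.1-s intensity frames, the 1-s
#' anticipation shift, the 0.85/0.15 refinement thresholds, 0.5-s
#' spectrogram windows with 1024 bins, the 20--200 Hz Dimitrov band, the
#' natural-log normalisation, the Holm family and the paired RoM test.
#'
#' @param ... Named overrides of nested entries, e.g.
#'   `pipeline_config(filter = list(order = 8))`.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter = list(low_hz = 20, high_hz = 200, order = 10,
                  order_convention = "per_pass"),
    segment = list(frame_s = 0.1, shift_s = 1.0, upper_frac = 0.85,
                   thresh_frac = 0.15, upper_mode = "max"),
    features = list(window_s = 0.5, n_bins = 1024,
                    window_fun = "rectangular", band = c(20, 200),
                    strict_indices = FALSE, log_base = "natural"),
    stats = list(holm_family = "per_variable", conf_level = 0.95,
                 variables = c("vrms_uV", "tzc_pct", "fmn_hz", "fmd_hz",
                               "log_fin")),
    rom = list(paired = TRUE),
    fs_emg = 2000, fs_mocap = 100)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override the [pipeline_config()] defaults;
#' everything else keeps its default.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("no such config file: %s", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full study pipeline
#'
#' For every exercise in the manifest: read the EMG, band-pass filter it,
#' compute the combined intensity, shift and refine the coarse marks, export
#' the refined marks for review, and extract the per-segment features. Then
#' fit the per-variable, per-muscle mixed models and the range-of-motion
#' summary, and write all result tables plus a run log to `out_dir`.
#' Per-exercise failures are isolated, logged and summarised; the run only
#' errors when no exercise succeeds.
#'
#' @param manifest Manifest data frame (see [read_manifest()]) or a path to
#'   a manifest CSV.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return List with `features`, `effects` (see [run_effects()]), `rom`
#'   (see [rom_summary()]), `marks` (refined, all exercises) and `failures`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feats <- list()
  marks_all <- list()
  motions <- list()
  failures <- list()

  for (i in seq_len(nrow(manifest))) {
    ex <- manifest[i, ]
    res <- tryCatch({
      meta <- list(subject = ex$subject, condition = ex$condition,
                   weight_kg = ex$weight_kg, exercise_id = ex$exercise_id)
      rec <- read_emg_csv(ex$emg_path, fs = config$fs_emg, meta = meta)
      rec <- bandpass_filter(rec,
                             low_hz = config$filter$low_hz,
                             high_hz = config$filter$high_hz,
                             order = config$filter$order,
                             order_convention = config$filter$order_convention)
      coarse <- read_marks_csv(ex$marks_path)
      shifted <- shift_marks(coarse, shift_s = config$segment$shift_s)
      intensity <- combined_intensity(rec, frame_s = config$segment$frame_s)
      refined <- refine_marks(intensity, shifted,
                              upper_frac = config$segment$upper_frac,
                              thresh_frac = config$segment$thresh_frac,
                              fs = rec$fs,
                              upper_mode = config$segment$upper_mode)
      fe <- extract_features(
        rec, refined,
        window_s = config$features$window_s,
        n_bins = config$features$n_bins,
        window_fun = config$features$window_fun,
        band = config$features$band,
        index_band = if (isTRUE(config$features$strict_indices)) {
          round(config$features$band / (config$fs_emg / (2 * config$features$n_bins)))
        },
        log_base = config$features$log_base)
      moc <- read_mocap_csv(ex$mocap_path, fs = config$fs_mocap, meta = meta)
      list(features = fe, marks = cbind(exercise_id = ex$exercise_id, refined),
           motion = moc)
    }, error = function(cnd) cnd)
    if (inherits(res, "condition")) {
      failures[[ex$exercise_id]] <- conditionMessage(res)
    } else {
      feats[[ex$exercise_id]] <- res$features
      marks_all[[ex$exercise_id]] <- res$marks
      motions[[ex$exercise_id]] <- res$motion
    }
  }
  if (!length(feats)) abort_input("every exercise failed; nothing to analyse")

  features <- do.call(rbind, c(feats, make.row.names = FALSE))
  marks <- do.call(rbind, c(marks_all, make.row.names = FALSE))
  effects <- run_effects(features,
                         variables = config$stats$variables,
                         holm_family = config$stats$holm_family,
                         conf_level = config$stats$conf_level)
  rom <- rom_summary(motions, paired = config$rom$paired)

  write_if <- function(x, name) {
    if (!is.null(x) && nrow(x)) data.table::fwrite(x, file.path(out_dir, name))
  }
  write_if(features, "features.csv")
  write_if(marks, "marks_refined.csv")
  write_if(effects$effects, "effects.csv")
  write_if(effects$curves, "curves_by_box.csv")
  write_if(effects$diagnostics, "residual_diagnostics.csv")
  write_if(rom$comparison, "rom.csv")
  write_if(rom$percentiles, "rom_percentiles.csv")

  log <- list(
    package = as.character(packageVersion("exolift")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_exercises = nrow(manifest), n_failed = length(failures),
    failures = failures,
    config = unclass(config))
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))

  if (length(failures)) {
    warning(sprintf("%d exercise(s) failed: %s", length(failures),
                    paste(names(failures), collapse = ", ")), call. = FALSE)
  }
  invisible(list(features = features, effects = effects, rom = rom,
                 marks = marks, failures = failures))
}
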