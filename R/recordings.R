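# Lightweight containers for the two time-series types the pipeline handles.

new_emg_recording <- function(samples, fs, muscles, meta = list()) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || fs <= 0) abort_config("`fs` must be positive")
  if (ncol(samples) != length(muscles)) {
    abort_input("one column per muscle label required")
  }
  colnames(samples) <- muscles
  structure(list(samples = samples, fs = fs, muscles = muscles, meta = meta),
            class = "emg_recording")
}

new_motion_recording <- function(angles, fs, coordinates, meta = list()) {
  angles <- as.matrix(angles)
  if (!is.numeric(fs) || fs <= 0) abort_config("`fs` must be positive")
  if (ncol(angles) != length(coordinates)) {
    abort_input("one column per coordinate label required")
  }
  if (anyDuplicated(coordinates)) abort_input("coordinate labels must be unique")
  colnames(angles) <- coordinates
  structure(list(angles = angles, fs = fs, coordinates = coordinates,
                 meta = meta),
            class = "motion_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d muscles @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  if (length(x$meta)) {
    cat("  ", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.motion_recording <- function(x, ...) {
  cat(sprintf("<motion_recording> %d samples x %d coordinates @ %g Hz\n",
              nrow(x$angles), ncol(x$angles), x$fs))
  invisible(x)
}

n_samples <- function(rec) {
  nrow(if (inherits(rec, "emg_recording")) rec$samples else rec$angles)
}
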