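# Per-lift segmentation: coarse motion-derived marks, the 1-s anticipation
# shift, and refinement on the combined RMS intensity trace.

#' Shift coarse mark starts earlier
#'
#' Relocates every coarse start mark `shift_s` seconds earlier, so the
#' myoelectrical activation that precedes the mechanical lift is captured.
#' End marks are unchanged. A shifted start is clamped to the previous box's
#' end when the shift would make intervals overlap; clamped boxes are
#' flagged.
#'
#' @param marks Data frame with columns `box`, `start_s`, `end_s` (and
#'   optionally `flag`).
#' @param shift_s Non-negative shift (s).
#' @return The marks with shifted starts and a `flag` column.
#' @export
shift_marks <- function(marks, shift_s = 1.0) {
  check_marks(marks)
  if (shift_s < 0) abort_config("`shift_s` must be non-negative")
  if (marks$start_s[1] < shift_s) {
    abort_input(sprintf(
      paste("first mark at %.2f s is too close to the recording start to",
            "shift by %.2f s; record (or simulate) a longer lead-in"),
      marks$start_s[1], shift_s))
  }
  out <- marks
  if (is.null(out$flag)) out$flag <- ""
  out$start_s <- out$start_s - shift_s
  for (i in seq_len(nrow(out))[-1]) {
    if (out$start_s[i] < out$end_s[i - 1]) {
      out$start_s[i] <- out$end_s[i - 1]
      out$flag[i] <- paste_flag(out$flag[i], "clamped")
    }
  }
  out
}

check_marks <- function(marks) {
  need <- c("box", "start_s", "end_s")
  if (!is.data.frame(marks) || !all(need %in% names(marks))) {
    abort_input("marks need columns box, start_s, end_s")
  }
  if (is.unsorted(marks$start_s, strictly = TRUE)) {
    abort_input("mark starts must be strictly increasing")
  }
  if (any(marks$end_s <= marks$start_s)) {
    abort_input("each mark must have end_s > start_s")
  }
  invisible(marks)
}

paste_flag <- function(flag, new) {
  if (is.na(flag) || !nzchar(flag)) new else paste(flag, new, sep = ";")
}

#' Combined normalised intensity of the four EMG channels
#'
#' The segmentation driver: the sum over channels of the squared frame RMS,
#' each channel normalised by its whole-exercise RMS so that no channel's
#' gain dominates the segmentation. Frames are non-overlapping windows of
#' `frame_s` seconds; a trailing partial frame is dropped.
#'
#' @param rec An `emg_recording`.
#' @param frame_s Frame length (s).
#' @return An `intensity_trace`: `values` (one per frame), `frame_s`,
#'   `n_frames`.
#' @export
combined_intensity <- function(rec, frame_s = 0.1) {
  if (!inherits(rec, "emg_recording")) {
    abort_input("`rec` must be an emg_recording")
  }
  flen <- round(frame_s * rec$fs)
  n <- nrow(rec$samples)
  nf <- floor(n / flen)
  if (nf < 1) abort_input("recording shorter than one intensity frame")
  total_vrms <- sqrt(colMeans(rec$samples^2))
  dead <- which(total_vrms == 0)
  if (length(dead)) {
    abort_input(sprintf("channel(s) with zero total RMS: %s",
                        paste(rec$muscles[dead], collapse = ", ")))
  }
  used <- rec$samples[seq_len(nf * flen), , drop = FALSE]
  vals <- rep(0, nf)
  frame_of <- rep(seq_len(nf), each = flen)
  for (m in seq_len(ncol(used))) {
    frame_ms <- rowsum(used[, m]^2, frame_of) / flen
    vals <- vals + frame_ms / total_vrms[m]^2  # (frame RMS / total RMS)^2
  }
  structure(list(values = as.numeric(vals), frame_s = frame_s, n_frames = nf),
            class = "intensity_trace")
}

#' Refine segment marks on the intensity trace
#'
#' Within each (shifted) coarse slice, the reference level `H` is the mean of
#' the intensity values above `upper_frac` of the slice maximum
#' (`upper_mode = "max"`, the default) or above the `upper_frac` quantile
#' (`upper_mode = "percentile"`). The threshold is `thresh_frac * H`; the
#' refined segment runs from the first to the last frame at or above it.
#' A slice whose every frame clears the threshold is refined to the whole
#' slice and flagged for review.
#'
#' @param intensity An [combined_intensity()] trace.
#' @param shifted Marks after [shift_marks()].
#' @param upper_frac Fraction defining the upper criterion.
#' @param thresh_frac Fraction of `H` used as detection threshold.
#' @param fs EMG sampling rate used to express refined marks in samples.
#' @param upper_mode Reference for the upper criterion (see Details).
#' @return Refined marks: `box`, `start_s`, `end_s`, `start_sample`,
#'   `end_sample`, `flag`.
#' @export
refine_marks <- function(intensity, shifted, upper_frac = 0.85,
                         thresh_frac = 0.15, fs = 2000,
                         upper_mode = c("max", "percentile")) {
  upper_mode <- match.arg(upper_mode)
  if (!inherits(intensity, "intensity_trace")) {
    abort_input("`intensity` must come from combined_intensity()")
  }
  check_marks(shifted)
  frame_s <- intensity$frame_s
  I <- intensity$values
  out <- shifted[, c("box", "start_s", "end_s")]
  out$start_sample <- out$end_sample <- NA_integer_
  out$flag <- if (is.null(shifted$flag)) "" else shifted$flag
  prev_end_frame <- 0L
  for (i in seq_len(nrow(out))) {
    f_lo <- floor(out$start_s[i] / frame_s) + 1L
    f_hi <- min(intensity$n_frames, ceiling(out$end_s[i] / frame_s))
    f_lo <- max(f_lo, prev_end_frame + 1L)
    if (f_lo > f_hi) {
      abort_segment(sprintf("box %d: slice contains no intensity frame",
                            out$box[i]))
    }
    sl <- I[f_lo:f_hi]
    if (max(sl) <= 0) {
      abort_segment(sprintf("box %d: flat intensity, cannot refine",
                            out$box[i]))
    }
    above <- if (upper_mode == "max") {
      sl[sl > upper_frac * max(sl)]
    } else {
      sl[sl > quantile(sl, upper_frac, names = FALSE)]
    }
    if (!length(above)) above <- max(sl)
    theta <- thresh_frac * mean(above)
    sel <- which(sl >= theta)
    if (length(sel) == length(sl)) {
      out$flag[i] <- paste_flag(out$flag[i], "all_above_threshold")
    }
    fa <- f_lo + min(sel) - 1L
    fb <- f_lo + max(sel) - 1L
    out$start_s[i] <- (fa - 1L) * frame_s
    out$end_s[i] <- fb * frame_s
    out$start_sample[i] <- as.integer(round((fa - 1L) * frame_s * fs)) + 1L
    out$end_sample[i] <- as.integer(round(fb * frame_s * fs))
    prev_end_frame <- fb
  }
  out
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d frames of %.2f s (range %.3g..%.3g)\n",
              x$n_frames, x$frame_s, min(x$values), max(x$values)))
  invisible(x)
}
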