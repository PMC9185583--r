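# EMG conditioning: zero-phase Butterworth band-pass.

#' Zero-phase Butterworth band-pass filter
#'
#' Conditions each EMG channel with an order-`order` Butterworth band-pass
#' applied forward and backward (zero phase, so burst boundaries are not
#' delayed). The defaults (20--200 Hz, order 10) remove movement artefacts
#' and limit the analysis bandwidth.
#'
#' `order` is the design order of the single-pass band-pass; the
#' forward--backward application doubles the effective attenuation
#' (`order_convention = "per_pass"`, the default). With
#' `order_convention = "overall"` the single pass uses `order / 2`; because a
#' Butterworth band-pass derived from the low-pass prototype has even order,
#' this convention requires `order` divisible by 4.
#'
#' Edge transients are handled by even-reflection padding (three periods of
#' the low cut-off, at least three filter lengths) before each pass.
#'
#' @param rec An `emg_recording`.
#' @param low_hz,high_hz Band edges (Hz), `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth design order (even).
#' @param order_convention `"per_pass"` or `"overall"` (see Details).
#' @return The filtered recording, same length and metadata.
#' @export
bandpass_filter <- function(rec, low_hz = 20, high_hz = 200, order = 10,
                            order_convention = c("per_pass", "overall")) {
  if (!inherits(rec, "emg_recording")) {
    abort_input("`rec` must be an emg_recording")
  }
  order_convention <- match.arg(order_convention)
  stopifnot_scalar_number(low_hz, "low_hz")
  stopifnot_scalar_number(high_hz, "high_hz")
  fs <- rec$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    abort_config("cut-offs must satisfy 0 < low_hz < high_hz < fs/2")
  }
  if (order_convention == "overall") {
    if (order %% 4 != 0) {
      abort_config("overall convention needs `order` divisible by 4")
    }
    order <- order / 2
  }
  if (order %% 2 != 0 || order < 2) {
    abort_config("`order` must be a positive even integer")
  }
  bf <- signal::butter(order / 2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  pad <- max(3L * (length(bf$a) - 1L), 3L * ceiling(fs / low_hz))
  n <- nrow(rec$samples)
  if (n <= pad + 1L) {
    abort_input(sprintf(
      "recording too short for edge padding (need > %d samples, have %d)",
      pad + 1L, n))
  }
  filtered <- apply(rec$samples, 2, zero_phase_filter, filt = bf, pad = pad)
  out <- rec
  out$samples <- filtered
  colnames(out$samples) <- rec$muscles
  out
}

# Forward-backward IIR filtering with even-reflection padding; the padding is
# stripped so the output has the input length.
zero_phase_filter <- function(x, filt, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  y <- as.numeric(signal::filter(filt, xp))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(pad + 1L):(pad + n)]
}
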