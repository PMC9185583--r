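# Per-segment activation and fatigue parameters: RMS amplitude,
# zero-crossing rate, spectrogram mean/median frequency, and the Dimitrov
# spectral fatigue index with per-exercise log normalisation.

#' Root-mean-square amplitude of a segment
#'
#' @param x Numeric segment (microvolt).
#' @return `sqrt(mean(x^2))`; positively homogeneous in the signal scale.
#' @export
vrms <- function(x) {
  if (!length(x)) abort_input("empty segment")
  sqrt(mean(x^2))
}

#' Zero-crossing rate of a segment (percent)
#'
#' Sign flips relative to the segment length: each flip contributes
#' `2 / N * 100`, so a strictly alternating signal approaches 200. Zero
#' samples take the sign of the previous non-zero sample, so quantised
#' baselines do not double-count flips.
#'
#' @param x Numeric segment.
#' @return Rate in percent, in `[0, 200]`.
#' @export
tzc <- function(x) {
  n <- length(x)
  if (n < 2) abort_input("zero-crossing rate needs at least two samples")
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(0)
  # carry the last non-zero sign forward (and the first one backward)
  idx <- cumsum(nz)
  first <- s[which(nz)[1]]
  filled <- c(first, s[nz])[idx + 1L]
  sum(abs(diff(filled))) / n * 100
}

#' Non-overlapping spectrogram of a segment
#'
#' Splits the segment into `floor(N / (fs * window_s))` non-overlapping
#' windows (trailing partial window dropped) and computes each window's
#' one-sided power spectrum on `n_bins` bins. Windows are zero-padded to
#' `2 * n_bins` points, so bin `k` maps to `k * fs / (2 * n_bins)` Hz; with
#' the defaults (0.5 s, 1024 bins, 2000 Hz) the bins span up to 1 kHz in
#' steps of 1000/1024 Hz. Power is scaled so that for each window the bin sum
#' plus the stored DC term equals the windowed time-domain energy (Parseval).
#'
#' @param x Numeric segment.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length (s).
#' @param n_bins Number of positive-frequency bins.
#' @param window_fun `"rectangular"` (the default; the parameters are defined
#'   on raw spectrogram power) or `"hann"`.
#' @return An `emg_spectrogram` (`sp`: L x n_bins matrix, `freq_hz`, `dc`,
#'   `df_hz`), or `NULL` with attribute `reason` when the segment is shorter
#'   than one window.
#' @export
emg_spectrogram <- function(x, fs, window_s = 0.5, n_bins = 1024,
                            window_fun = c("rectangular", "hann")) {
  window_fun <- match.arg(window_fun)
  wlen <- round(fs * window_s)
  L <- floor(length(x) / wlen)
  if (L < 1) {
    return(missing_value(sprintf(
      "segment of %d samples shorter than one %g-s window",
      length(x), window_s)))
  }
  nfft <- 2L * n_bins
  if (wlen > nfft) abort_config("window longer than 2 * n_bins samples")
  win <- switch(window_fun,
    rectangular = rep(1, wlen),
    hann = 0.5 * (1 - cos(2 * pi * seq(0, wlen - 1) / (wlen - 1))))
  sp <- matrix(0, nrow = L, ncol = n_bins)
  dc <- numeric(L)
  for (j in seq_len(L)) {
    xw <- x[((j - 1L) * wlen + 1L):(j * wlen)] * win
    X <- fft(c(xw, numeric(nfft - wlen)))
    p <- Mod(X)^2 / nfft
    dc[j] <- p[1L]
    sp[j, ] <- c(2 * p[2:n_bins], p[n_bins + 1L])
  }
  structure(list(sp = sp, freq_hz = seq_len(n_bins) * fs / nfft, dc = dc,
                 df_hz = fs / nfft, window_s = window_s, fs = fs),
            class = "emg_spectrogram")
}

valid_windows <- function(sp) which(rowSums(sp$sp) > 0)

#' Mean power frequency of a spectrogram
#'
#' Average over windows of the power-weighted mean frequency. Windows with
#' zero total power are excluded; if none remain the value is `NA` with a
#' `reason` attribute.
#'
#' @param sp An [emg_spectrogram()].
#' @return Mean frequency (Hz).
#' @export
fmn <- function(sp) {
  if (!inherits(sp, "emg_spectrogram")) {
    return(missing_value(attr(sp, "reason")))
  }
  ok <- valid_windows(sp)
  if (!length(ok)) return(missing_value("all spectrogram windows empty"))
  per <- vapply(ok, function(j) {
    w <- sp$sp[j, ]
    sum(sp$freq_hz * w) / sum(w)
  }, numeric(1))
  mean(per)
}

#' Median power frequency of a spectrogram
#'
#' Average over windows of the frequency of the bin that splits each
#' window's cumulative power in half.
#'
#' @inheritParams fmn
#' @return Median frequency (Hz).
#' @export
fmd <- function(sp) {
  if (!inherits(sp, "emg_spectrogram")) {
    return(missing_value(attr(sp, "reason")))
  }
  ok <- valid_windows(sp)
  if (!length(ok)) return(missing_value("all spectrogram windows empty"))
  per <- vapply(ok, function(j) {
    w <- sp$sp[j, ]
    d <- which(cumsum(w) >= sum(w) / 2)[1]
    sp$freq_hz[d]
  }, numeric(1))
  mean(per)
}

missing_value <- function(reason) {
  out <- NA_real_
  attr(out, "reason") <- reason
  out
}

#' Spectral marginal (summed power spectral density)
#'
#' Sums the spectrogram over time windows, giving the PSD the Dimitrov index
#' is computed from.
#'
#' @inheritParams fmn
#' @return A `spectral_marginal`: `psd`, `freq_hz`, `df_hz`.
#' @export
spectral_marginal <- function(sp) {
  if (!inherits(sp, "emg_spectrogram")) {
    return(missing_value(attr(sp, "reason")))
  }
  structure(list(psd = colSums(sp$sp), freq_hz = sp$freq_hz, df_hz = sp$df_hz),
            class = "spectral_marginal")
}

#' Dimitrov spectral fatigue index
#'
#' Ratio of the order -1 to the order +5 spectral moments of the PSD over the
#' analysis band, expressed in physical frequency:
#' `FI = sum(PSD/f) / sum(PSD * f^5)` over the band. The index grows steeply
#' (as `f0^-6` for a narrowband spectrum at `f0`) when power shifts towards
#' low frequencies, which makes it highly sensitive to peripheral fatigue.
#'
#' The band is selected by physical frequency (default 20--200 Hz). With the
#' default bin mapping (1024 bins to 1 kHz) the corresponding bin indices are
#' 21..204; `index_band` instead selects literal bin indices (e.g.
#' `c(41, 410)`).
#'
#' @param marg A [spectral_marginal()].
#' @param band Band edges in Hz.
#' @param index_band Optional integer bin range overriding `band`.
#' @return The index (Hz^-6 scale), or `NA` with a reason when the band holds
#'   no power.
#' @export
dimitrov_fi <- function(marg, band = c(20, 200), index_band = NULL) {
  if (!inherits(marg, "spectral_marginal")) {
    return(missing_value(attr(marg, "reason")))
  }
  sel <- if (is.null(index_band)) {
    marg$freq_hz >= band[1] & marg$freq_hz <= band[2]
  } else {
    seq_along(marg$freq_hz) >= index_band[1] &
      seq_along(marg$freq_hz) <= index_band[2]
  }
  p <- marg$psd[sel]
  f <- marg$freq_hz[sel]
  if (sum(p) <= 0) return(missing_value("no power in the analysis band"))
  sum(p / f) / sum(p * f^5)
}

#' Normalised logarithmic Dimitrov index
#'
#' Within each group (one exercise of one participant, per muscle), divides
#' the per-segment index by the group minimum and takes the logarithm, so the
#' least-fatigued segment maps to 0 and the values track the fatigue build-up
#' across the exercise. Missing index values stay missing; the minimum is
#' taken over the remaining segments.
#'
#' @param fi Numeric vector of per-segment indices (> 0 where present).
#' @param group Grouping vector (same length as `fi`).
#' @param log_base `"natural"` (default) or `"10"`; recorded by callers in
#'   output metadata since percent effects depend on the scale.
#' @return `log(fi / min(fi))` per group.
#' @export
normalize_log_fi <- function(fi, group = rep(1L, length(fi)),
                             log_base = c("natural", "10")) {
  log_base <- match.arg(log_base)
  if (length(group) != length(fi)) abort_input("`group` must match `fi`")
  out <- rep(NA_real_, length(fi))
  for (g in split(seq_along(fi), group)) {
    vals <- fi[g]
    ok <- is.finite(vals)
    if (!any(ok)) next
    if (any(vals[ok] <= 0)) abort_input("Dimitrov index must be positive")
    lo <- min(vals[ok])
    out[g[ok]] <- log(vals[ok] / lo)
  }
  if (log_base == "10") out <- out / log(10)
  out
}

#' Extract all per-segment features of one exercise
#'
#' One row per (box, muscle) with the six parameters: VRMS, TZC, FMN, FMD,
#' the Dimitrov index FI, and its normalised logarithm (normalised within
#' this exercise, per muscle). Per-segment failures (e.g. a segment shorter
#' than one spectrogram window) yield missing values with a flag; the
#' exercise is never aborted.
#'
#' @param rec A (filtered) `emg_recording`.
#' @param marks Refined marks with `start_sample`, `end_sample` (falls back
#'   to `start_s`/`end_s` at the recording rate).
#' @param window_s,n_bins,window_fun Passed to [emg_spectrogram()].
#' @param band,index_band Passed to [dimitrov_fi()].
#' @param log_base Passed to [normalize_log_fi()].
#' @return Data frame: `subject`, `condition`, `weight_kg`, `exercise_id`,
#'   `box`, `muscle`, `vrms_uV`, `tzc_pct`, `fmn_hz`, `fmd_hz`, `fi`,
#'   `log_fin`, `flag`.
#' @export
extract_features <- function(rec, marks, window_s = 0.5, n_bins = 1024,
                             window_fun = "rectangular", band = c(20, 200),
                             index_band = NULL, log_base = "natural") {
  if (!inherits(rec, "emg_recording")) {
    abort_input("`rec` must be an emg_recording")
  }
  if (is.null(marks$start_sample)) {
    marks$start_sample <- round(marks$start_s * rec$fs) + 1L
    marks$end_sample <- round(marks$end_s * rec$fs)
  }
  meta <- rec$meta
  rows <- vector("list", nrow(marks) * length(rec$muscles))
  r <- 0L
  for (b in seq_len(nrow(marks))) {
    i0 <- max(1L, marks$start_sample[b])
    i1 <- min(nrow(rec$samples), marks$end_sample[b])
    for (m in seq_along(rec$muscles)) {
      seg <- rec$samples[i0:i1, m]
      sp <- emg_spectrogram(seg, rec$fs, window_s = window_s, n_bins = n_bins,
                            window_fun = window_fun)
      fi_val <- dimitrov_fi(spectral_marginal(sp), band = band,
                            index_band = index_band)
      flag <- attr(fi_val, "reason")
      r <- r + 1L
      rows[[r]] <- data.frame(
        subject = meta$subject %||% NA, condition = meta$condition %||% NA,
        weight_kg = meta$weight_kg %||% NA,
        exercise_id = meta$exercise_id %||% NA,
        box = marks$box[b], muscle = rec$muscles[m],
        vrms_uV = vrms(seg), tzc_pct = tzc(seg),
        fmn_hz = as.numeric(fmn(sp)), fmd_hz = as.numeric(fmd(sp)),
        fi = as.numeric(fi_val), log_fin = NA_real_,
        flag = flag %||% "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$log_fin <- normalize_log_fi(out$fi, group = out$muscle,
                                  log_base = log_base)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
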