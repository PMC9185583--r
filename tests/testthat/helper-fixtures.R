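# Shared fixtures: small study configurations and independent brute-force
# oracles for the spectral parameters.

small_config <- function(...) {
  synth_config(n_subjects = 2, weights_kg = 8, n_boxes = 4, seed = 11, ...)
}

# Idealised generator settings matching the noise-free recovery examples:
# no baseline noise, no fatigue drift, no condition effect, no residual.
ideal_config <- function(...) {
  synth_config(noise_floor_uV = 0, fatigue_amplitude_slope = 0,
               fatigue_spectral_slope = 0, exo_amplitude_effect = 0,
               exo_fatigue_attenuation = 0, residual_log_sd = 0, ...)
}

make_rec <- function(mat, fs = 2000,
                     muscles = paste0("m", seq_len(ncol(mat)))) {
  exolift:::new_emg_recording(mat, fs = fs, muscles = muscles)
}

tone_rec <- function(freq_hz, dur_s = 10, fs = 2000, amp = 1, n_chan = 1) {
  t <- seq(0, dur_s, by = 1 / fs)
  make_rec(matrix(rep(amp * sin(2 * pi * freq_hz * t), n_chan),
                  ncol = n_chan), fs = fs)
}

# Brute-force oracles written directly from the definitions, independent of
# the implementation's vectorised paths.
oracle_fmn <- function(sp) {
  vals <- c()
  for (j in seq_len(nrow(sp$sp))) {
    tot <- 0; acc <- 0
    for (k in seq_len(ncol(sp$sp))) {
      tot <- tot + sp$sp[j, k]
      acc <- acc + k * sp$df_hz * sp$sp[j, k]
    }
    if (tot > 0) vals <- c(vals, acc / tot)
  }
  mean(vals)
}

oracle_fmd <- function(sp) {
  vals <- c()
  for (j in seq_len(nrow(sp$sp))) {
    tot <- sum(sp$sp[j, ])
    if (tot <= 0) next
    run <- 0
    for (k in seq_len(ncol(sp$sp))) {
      run <- run + sp$sp[j, k]
      if (run >= tot / 2) { vals <- c(vals, k * sp$df_hz); break }
    }
  }
  mean(vals)
}

oracle_fi <- function(psd, df_hz, band = c(20, 200)) {
  num <- 0; den <- 0
  for (k in seq_along(psd)) {
    f <- k * df_hz
    if (f >= band[1] && f <= band[2]) {
      num <- num + psd[k] / k
      den <- den + psd[k] * k^5
    }
  }
  num / den * df_hz^-6
}

random_spectrogram <- function(L = 3, M = 1024, df_hz = 1000 / 1024) {
  structure(list(sp = matrix(stats::rexp(L * M), nrow = L),
                 freq_hz = seq_len(M) * df_hz, dc = numeric(L),
                 df_hz = df_hz, window_s = 0.5, fs = 2 * M * df_hz),
            class = "emg_spectrogram")
}
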