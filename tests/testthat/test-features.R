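df_default <- 1000 / 1024  # bin width at 2000 Hz, 1024 bins

test_that("vrms matches hand-computed values and is homogeneous", {
  expect_equal(vrms(rep(2, 50)), 2)
  expect_equal(vrms(c(3, -3, 3, -3)), 3)
  expect_equal(vrms(c(1, 2, 3, 4)), sqrt(7.5))
  set.seed(1)
  x <- rnorm(100)
  expect_equal(vrms(-2.5 * x), 2.5 * vrms(x))
  expect_error(vrms(numeric(0)), class = "exolift_input_error")
})

test_that("zero-crossing rate counts sign flips relative to segment length", {
  expect_equal(tzc(rep(4, 10)), 0)
  expect_equal(tzc(c(1, -1, 1, -1)), 150)  # three flips x 2 / 4 x 100
  t <- (0:1999) / 2000
  tone <- sin(2 * pi * 100 * t - 0.3)  # no sample exactly zero; 200 crossings
  expect_equal(tzc(tone), 20)
  # zero samples take the neighbouring sign: no double-counted flips
  expect_equal(tzc(c(1, 0, 1, 0, 1)), 0)
  expect_equal(tzc(c(1, 0, -1, 0, 1)), 80)  # two flips x 2 / 5 x 100
  expect_equal(tzc(c(0, 0, 2, 1)), 0)
  expect_error(tzc(1), class = "exolift_input_error")
})

test_that("spectrogram layout: non-overlapping 0.5-s windows, 1024 bins to 1 kHz", {
  set.seed(2)
  sp <- emg_spectrogram(rnorm(4000), fs = 2000)
  expect_equal(nrow(sp$sp), 4L)
  expect_equal(ncol(sp$sp), 1024L)
  expect_equal(sp$df_hz, df_default)
  expect_equal(max(sp$freq_hz), 1000)
  # trailing partial window dropped
  expect_equal(nrow(emg_spectrogram(rnorm(4999), fs = 2000)$sp), 4L)
  # too short for one window: missing with reason, propagated downstream
  short <- emg_spectrogram(rnorm(500), fs = 2000)
  expect_true(is.na(short))
  expect_match(attr(short, "reason"), "shorter")
  expect_true(is.na(fmn(short)))
  expect_true(is.na(dimitrov_fi(spectral_marginal(short))))
})

test_that("spectrogram power satisfies Parseval per window", {
  set.seed(3)
  x <- rnorm(2000)
  sp <- emg_spectrogram(x, fs = 2000)
  for (j in 1:2) {
    xw <- x[((j - 1) * 1000 + 1):(j * 1000)]
    expect_equal(sum(sp$sp[j, ]) + sp$dc[j], sum(xw^2), tolerance = 1e-9)
  }
})

test_that("a pure tone concentrates every window at its frequency", {
  t <- (0:3999) / 2000
  sp <- emg_spectrogram(sin(2 * pi * 100 * t), fs = 2000)
  peaks <- sp$freq_hz[apply(sp$sp, 1, which.max)]
  expect_true(all(abs(peaks - 100) <= sp$df_hz))
})

test_that("mean frequency: tones, symmetry, flat spectrum", {
  t <- (0:3999) / 2000
  sp <- emg_spectrogram(sin(2 * pi * 100 * t), fs = 2000)
  expect_lt(abs(fmn(sp) - 100), df_default)

  two <- emg_spectrogram(sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t),
                         fs = 2000)
  expect_lt(abs(fmn(two) - 100), df_default)

  flat <- random_spectrogram(L = 1)
  flat$sp[] <- 1
  expect_equal(fmn(flat), (1024 + 1) / 2 * df_default)
})

test_that("median frequency: tones and single-bin spectra", {
  t <- (0:3999) / 2000
  sp <- emg_spectrogram(sin(2 * pi * 100 * t), fs = 2000)
  expect_lt(abs(fmd(sp) - 100), df_default)

  onebin <- random_spectrogram(L = 2)
  onebin$sp[] <- 0
  onebin$sp[, 300] <- c(5, 7)
  expect_equal(fmd(onebin), 300 * df_default)
  expect_equal(fmn(onebin), 300 * df_default)

  two <- emg_spectrogram(sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t),
                         fs = 2000)
  expect_equal(fmd(two), oracle_fmd(two))
  expect_gt(fmd(two), 50)
  expect_lt(fmd(two), 150)
})

test_that("empty windows are excluded; all-empty spectra go missing", {
  sp <- random_spectrogram(L = 3)
  sp$sp[2, ] <- 0
  ref <- sp
  ref$sp <- ref$sp[c(1, 3), , drop = FALSE]
  expect_equal(fmn(sp), oracle_fmn(ref))
  sp$sp[] <- 0
  expect_true(is.na(fmn(sp)))
  expect_match(attr(fmn(sp), "reason"), "empty")
})

test_that("Dimitrov index: single-bin algebra and the f^-6 scaling law", {
  m <- list(psd = numeric(1024), freq_hz = seq_len(1024) * df_default,
            df_hz = df_default)
  class(m) <- "spectral_marginal"
  k0 <- 103  # ~100.6 Hz
  m$psd[k0] <- 4
  f0 <- m$freq_hz[k0]
  expect_equal(dimitrov_fi(m), f0^-6, tolerance = 1e-12)

  # narrowband translation 100 -> 50 Hz multiplies FI by ~2^6
  g1 <- list(psd = exp(-(m$freq_hz - 100)^2 / 2), freq_hz = m$freq_hz,
             df_hz = df_default)
  g2 <- list(psd = exp(-(m$freq_hz - 50)^2 / 2), freq_hz = m$freq_hz,
             df_hz = df_default)
  class(g1) <- class(g2) <- "spectral_marginal"
  expect_equal(dimitrov_fi(g2) / dimitrov_fi(g1), 64, tolerance = 0.01)

  m$psd[] <- 0
  expect_true(is.na(dimitrov_fi(m)))
})

test_that("FI decreases monotonically as a narrowband spectrum moves up", {
  freq <- seq_len(1024) * df_default
  fis <- vapply(seq(40, 180, by = 20), function(c0) {
    m <- structure(list(psd = exp(-(freq - c0)^2 / 8), freq_hz = freq,
                        df_hz = df_default), class = "spectral_marginal")
    dimitrov_fi(m)
  }, numeric(1))
  expect_true(all(diff(fis) < 0))
})

test_that("strict literal band indices are available", {
  set.seed(9)
  m <- spectral_marginal(random_spectrogram())
  lit <- dimitrov_fi(m, index_band = c(41, 410))
  phys <- dimitrov_fi(m)
  sel <- 41:410
  expect_equal(lit, sum(m$psd[sel] / m$freq_hz[sel]) /
                 sum(m$psd[sel] * m$freq_hz[sel]^5))
  # the literal 40--400 Hz band weighs high frequencies far more heavily
  expect_gt(phys / lit, 10)
})

test_that("log normalisation maps the per-group minimum to zero", {
  expect_equal(normalize_log_fi(c(1, 2, 4)), log(c(1, 2, 4)))
  expect_equal(normalize_log_fi(rep(3, 5)), rep(0, 5))
  expect_equal(normalize_log_fi(7), 0)
  out <- normalize_log_fi(c(1, 2, 4, 10, 20), group = c(1, 1, 1, 2, 2))
  expect_equal(out, c(0, log(2), log(4), 0, log(2)))
  # missing values are skipped, not propagated to the group
  out <- normalize_log_fi(c(NA, 2, 8), group = rep(1, 3))
  expect_equal(out, c(NA, 0, log(4)))
  expect_equal(normalize_log_fi(c(1, 100), log_base = "10"), c(0, 2))
})

test_that("scaling a segment moves VRMS only", {
  set.seed(4)
  x <- rnorm(4000)
  sp1 <- emg_spectrogram(x, fs = 2000)
  sp2 <- emg_spectrogram(5 * x, fs = 2000)
  expect_equal(vrms(5 * x), 5 * vrms(x))
  expect_equal(tzc(5 * x), tzc(x))
  expect_equal(fmn(sp2), fmn(sp1))
  expect_equal(fmd(sp2), fmd(sp1))
  expect_equal(dimitrov_fi(spectral_marginal(sp2)),
               dimitrov_fi(spectral_marginal(sp1)))
})

test_that("extract_features yields one row per box and muscle", {
  cfg <- small_config()
  g <- generate_emg(cfg, 2, "exo", 8)
  fe <- extract_features(g$recording, g$truth$intervals)
  expect_equal(nrow(fe), cfg$n_boxes * length(cfg$muscles))
  expect_true(all(is.finite(fe$vrms_uV)))
  expect_true(all(is.finite(fe$log_fin)))
  expect_true(all(fe$log_fin >= 0))
  # minimum of each muscle group maps to zero
  expect_equal(as.numeric(tapply(fe$log_fin, fe$muscle, min)), rep(0, 4))
  # determinism
  fe2 <- extract_features(g$recording, g$truth$intervals)
  expect_identical(fe, fe2)
})
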