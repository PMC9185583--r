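test_that("configuration invariants are enforced", {
  expect_error(synth_config(seed = 0), class = "exolift_config_error")
  expect_error(synth_config(seed = -3), class = "exolift_config_error")
  expect_error(synth_config(seed = 2.5), class = "exolift_config_error")
  expect_error(synth_config(cadence_s = 2, burst_duration_s = 3),
               class = "exolift_config_error")
  expect_error(synth_config(subject_variance_share = 1),
               class = "exolift_config_error")
  expect_error(synth_config(base_amplitude_uV = c(-1, 1, 1, 1)),
               class = "exolift_config_error")
  expect_error(synth_config(fs_emg = 200), class = "exolift_config_error")
  expect_error(synth_config(base_amplitude_uV = c(1, 2)),
               class = "exolift_config_error")
})

test_that("invalid exercise requests are rejected", {
  cfg <- small_config()
  expect_error(generate_emg(cfg, 99, "noexo", 8), class = "exolift_input_error")
  expect_error(generate_emg(cfg, 1, "sometimes", 8),
               class = "exolift_input_error")
  expect_error(generate_emg(cfg, 1, "noexo", 12), class = "exolift_input_error")
})

test_that("generation is deterministic and bit-identical given the seed", {
  cfg <- small_config()
  a <- generate_emg(cfg, 1, "exo", 8)
  b <- generate_emg(cfg, 1, "exo", 8)
  expect_identical(a, b)
  m1 <- generate_mocap(cfg, 1, "exo", 8)
  m2 <- generate_mocap(cfg, 1, "exo", 8)
  expect_identical(m1, m2)
  # different exercises differ
  expect_false(identical(a$recording$samples,
                         generate_emg(cfg, 2, "exo", 8)$recording$samples))
})

test_that("truth intervals are disjoint, ordered, at the configured cadence", {
  cfg <- synth_config(seed = 5)
  iv <- generate_emg(cfg, 1, "noexo", 7)$truth$intervals
  expect_equal(nrow(iv), 16L)
  expect_equal(diff(iv$start_s), rep(6, 15))
  expect_true(all(iv$end_s - iv$start_s == cfg$burst_duration_s))
  expect_true(all(head(iv$end_s, -1) < tail(iv$start_s, -1)))
})

test_that("burst RMS matches the subject-scaled target under ideal settings", {
  for (seed in 1:5) {
    cfg <- ideal_config(n_subjects = 2, weights_kg = 8, n_boxes = 4,
                        seed = seed)
    g <- generate_emg(cfg, 1, "noexo", 8)
    u <- subject_factor(cfg, 1)
    iv <- g$truth$intervals
    for (m in seq_along(cfg$muscles)) {
      target <- cfg$base_amplitude_uV[[m]] * u
      for (b in seq_len(nrow(iv))) {
        seg <- g$recording$samples[
          (round(iv$start_s[b] * cfg$fs_emg) + 1):
            round(iv$end_s[b] * cfg$fs_emg), m]
        expect_lt(abs(vrms(seg) - target) / target, 0.05)
      }
    }
  }
})

test_that("a -10% exoskeleton amplitude effect shows as a 0.90 VRMS ratio", {
  cfg <- synth_config(exo_amplitude_effect = -0.10,
                      exo_fatigue_attenuation = 0, seed = 21)
  fr <- simulate_feature_frame(cfg, "gluteus")
  ratio <- mean(fr$vrms_uV[fr$exo == "exo"]) /
    mean(fr$vrms_uV[fr$exo == "noexo"])
  expect_lt(abs(ratio - 0.90), 0.035)
})

test_that("realised burst spectra centre on the configured frequency", {
  cfg <- ideal_config(n_subjects = 1, weights_kg = 8, n_boxes = 4, seed = 8)
  g <- generate_emg(cfg, 1, "noexo", 8)
  iv <- g$truth$intervals
  # independent periodogram oracle: power-weighted mean frequency of raw FFT
  for (m in seq_along(cfg$muscles)) {
    for (b in seq_len(nrow(iv))) {
      seg <- g$recording$samples[
        (round(iv$start_s[b] * cfg$fs_emg) + 1):
          round(iv$end_s[b] * cfg$fs_emg), m]
      n <- length(seg)
      p <- Mod(fft(seg))^2
      half <- 2:(n %/% 2)
      f <- (half - 1) * cfg$fs_emg / n
      centre <- sum(f * p[half]) / sum(p[half])
      expect_lt(abs(centre - cfg$base_center_freq_hz[[m]]) /
                  cfg$base_center_freq_hz[[m]], 0.05)
    }
  }
})

test_that("between-subject share of log burst amplitude hits its target", {
  shares <- vapply(1:50, function(s) {
    cfg <- synth_config(n_subjects = 8, seed = 100 + s)
    fr <- simulate_feature_frame(cfg, "erector_spinae")
    fit <- fit_mixed(data.frame(
      y = log(fr$vrms_uV), exo = factor(fr$exo, c("noexo", "exo")),
      box = factor(fr$box), weight = factor(fr$weight_kg),
      user = factor(fr$user)))
    icc(fit)
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.5), 0.07)
})

test_that("mocap traces carry one excursion per lift and coarse marks", {
  cfg <- small_config()
  moc <- generate_mocap(cfg, 1, "noexo", 8)
  expect_equal(nrow(moc$marks), cfg$n_boxes)
  expect_true(all(moc$marks$end_s > moc$marks$start_s))
  expect_equal(ncol(moc$recording$angles), length(cfg$rom_coordinates))
  # marks sit on the motion sampling grid
  expect_equal(moc$marks$start_s, round(moc$marks$start_s * 100) / 100)
})

test_that("zero rom effects give equal PRoM across conditions up to noise", {
  cfg <- small_config(rom_effects = c(lumbar_rotation = 0))
  a <- generate_mocap(cfg, 1, "noexo", 8)$recording$angles[, "lumbar_rotation"]
  b <- generate_mocap(cfg, 1, "exo", 8)$recording$angles[, "lumbar_rotation"]
  pa <- rom_percentiles(a); pb <- rom_percentiles(b)
  ra <- prom(pa[["P5"]], pa[["P95"]]); rb <- prom(pb[["P5"]], pb[["P95"]])
  expect_lt(abs(ra - rb) / ra, 0.05)
})

test_that("simulate_study writes a complete, readable file set", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_subjects = 1, weights_kg = 8, n_boxes = 2,
                      seed = 4)
  mf <- simulate_study(cfg, dir)
  expect_equal(nrow(mf), 2L)  # 1 subject x 2 conditions x 1 weight
  expect_true(all(file.exists(mf$emg_path)))
  expect_true(all(file.exists(mf$mocap_path)))
  expect_true(all(file.exists(mf$marks_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  rec <- read_emg_csv(mf$emg_path[1], fs = cfg$fs_emg)
  orig <- generate_emg(cfg, 1, "noexo", 8)$recording
  expect_equal(rec$samples, orig$samples, tolerance = 1e-6, ignore_attr = TRUE)
})
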