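# Synthetic study generator: band-limited Gaussian-noise EMG bursts and
# joint-angle excursions with a ground-truth record for every stage.

#' Configuration of the synthetic lifting study
#'
#' Builds the parameter set for the synthetic EMG and joint-angle generator.
#' The defaults emulate the laboratory scenario the analysis targets:
#' 8 subjects lifting three pallets of 16 boxes (7, 8 and 9 kg) at a 6-s
#' cadence, with and without a passive lumbar exoskeleton, four monitored
#' muscles at 2000 Hz and joint angles at 100 Hz.
#'
#' Each lift is a burst of band-limited Gaussian noise (band-pass of width
#' `bandwidth_hz` around the muscle's centre frequency) under a
#' raised-cosine-tapered envelope. Burst `b` of muscle `m` has target RMS
#' amplitude
#' `A0_m * u_s * (1 + amp_slope * r_b * att_c) * (1 + effect_cm) * w(kg)` and
#' centre frequency `f0_m * (1 - freq_slope * r_b * att_c)`, where
#' `r_b = (b-1)/(n_boxes-1)` is the fatigue ramp, `u_s` a lognormal subject
#' factor, `att_c = 1 - exo_fatigue_attenuation_m` under the exoskeleton
#' (1 otherwise), `effect_cm` the exoskeleton amplitude effect (0 without),
#' and `w(kg) = 1 + weight_gain_per_kg * (kg - min(weights_kg))`.
#'
#' The realised per-burst amplitude multiplies the target by
#' `exp(rnorm(1, 0, residual_log_sd))`; the subject factor is
#' `exp(sigma_u * z_s)` with `sigma_u = residual_log_sd *
#' sqrt(share / (1 - share))` so that the between-subject share of
#' log-amplitude variance equals `subject_variance_share`.
#'
#' @param n_subjects Number of subjects.
#' @param weights_kg Box weights (kg), one exercise per weight and condition.
#' @param n_boxes Lifts per exercise.
#' @param cadence_s Seconds between consecutive lift starts.
#' @param burst_duration_s Active EMG burst duration within each cycle (s).
#' @param fs_emg EMG sampling rate (Hz).
#' @param fs_mocap Joint-angle sampling rate (Hz).
#' @param muscles Ordered muscle labels.
#' @param base_amplitude_uV Baseline burst RMS amplitude per muscle (microvolt).
#' @param base_center_freq_hz Baseline spectral centre per muscle (Hz).
#' @param bandwidth_hz Full width of the shaping band (Hz).
#' @param fatigue_amplitude_slope Fractional amplitude increase from box 1 to
#'   box `n_boxes` (fatigue drift).
#' @param fatigue_spectral_slope Fractional centre-frequency decrease from box
#'   1 to box `n_boxes` (spectral compression).
#' @param exo_amplitude_effect Per-muscle fractional amplitude change under
#'   the exoskeleton (negative = reduction).
#' @param exo_fatigue_attenuation Per-muscle fraction by which the exoskeleton
#'   slows both fatigue slopes.
#' @param subject_variance_share Target between-subject share of log burst
#'   amplitude variance, in `[0, 1)`.
#' @param residual_log_sd Log-sd of the per-burst residual amplitude factor.
#' @param noise_floor_uV RMS of the additive white baseline noise (microvolt).
#' @param weight_gain_per_kg Amplitude gain per kg above the lightest box.
#' @param mech_delay_s Delay from EMG burst onset to the motion-derived mark
#'   (myoelectric activation precedes mechanical activation).
#' @param lead_in_s,lead_out_s Baseline-only padding before box 1 / after the
#'   last box (s).
#' @param envelope_ramp_s Raised-cosine ramp length of the burst envelope (s).
#' @param rom_coordinates Joint-coordinate labels of the motion traces.
#' @param rom_base_amplitude_deg Peak excursion per coordinate (degrees).
#' @param rom_effects Per-coordinate fractional change of excursion range
#'   under the exoskeleton (negative = restricted motion).
#' @param rom_noise_sd_deg Additive angle noise sd (degrees).
#' @param seed Positive integer seed; all generated exercises are
#'   deterministic functions of `(seed, subject, condition, weight)`.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8,
                         weights_kg = c(7, 8, 9),
                         n_boxes = 16,
                         cadence_s = 6,
                         burst_duration_s = 2,
                         fs_emg = 2000,
                         fs_mocap = 100,
                         muscles = c("erector_spinae", "gluteus",
                                     "quadriceps", "semitendinosus"),
                         base_amplitude_uV = c(60, 40, 50, 45),
                         base_center_freq_hz = c(75, 85, 90, 95),
                         bandwidth_hz = 40,
                         fatigue_amplitude_slope = 0.20,
                         fatigue_spectral_slope = 0.10,
                         exo_amplitude_effect = c(erector_spinae = -0.08,
                                                  gluteus = -0.05,
                                                  quadriceps = -0.04,
                                                  semitendinosus = -0.14),
                         exo_fatigue_attenuation = c(erector_spinae = 0.25,
                                                     gluteus = 0.25,
                                                     quadriceps = 0,
                                                     semitendinosus = 0.25),
                         subject_variance_share = 0.5,
                         residual_log_sd = 0.15,
                         noise_floor_uV = 1,
                         weight_gain_per_kg = 0.05,
                         mech_delay_s = 0.5,
                         lead_in_s = 2,
                         lead_out_s = 2,
                         envelope_ramp_s = 0.1,
                         rom_coordinates = c("lumbar_flexion_extension",
                                             "lumbar_rotation",
                                             "hip_flexion_right",
                                             "hip_flexion_left",
                                             "hip_rotation_right",
                                             "hip_rotation_left",
                                             "knee_flexion_right",
                                             "knee_flexion_left"),
                         rom_base_amplitude_deg = c(60, 20, 80, 80,
                                                    15, 15, 70, 70),
                         rom_effects = c(lumbar_flexion_extension = -0.03,
                                         lumbar_rotation = -0.39,
                                         hip_flexion_right = 0,
                                         hip_flexion_left = 0,
                                         hip_rotation_right = 0,
                                         hip_rotation_left = 0,
                                         knee_flexion_right = 0,
                                         knee_flexion_left = 0),
                         rom_noise_sd_deg = 0.3,
                         seed = 1) {
  nm <- length(muscles)
  rep_muscle <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, nm)
    if (length(x) != nm) {
      abort_config(sprintf("`%s` must have one value per muscle", name))
    }
    setNames(as.numeric(x), muscles)
  }

  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed <= 0 || seed != round(seed)) {
    abort_config("`seed` must be a positive integer")
  }
  if (n_subjects < 1 || n_boxes < 1) {
    abort_config("`n_subjects` and `n_boxes` must be at least 1")
  }
  if (!(cadence_s > burst_duration_s && burst_duration_s > 0)) {
    abort_config("need cadence_s > burst_duration_s > 0")
  }
  if (subject_variance_share < 0 || subject_variance_share >= 1) {
    abort_config("`subject_variance_share` must lie in [0, 1)")
  }
  base_amplitude_uV <- rep_muscle(base_amplitude_uV, "base_amplitude_uV")
  base_center_freq_hz <- rep_muscle(base_center_freq_hz, "base_center_freq_hz")
  exo_amplitude_effect <- rep_muscle(exo_amplitude_effect,
                                     "exo_amplitude_effect")
  exo_fatigue_attenuation <- rep_muscle(exo_fatigue_attenuation,
                                        "exo_fatigue_attenuation")
  if (any(base_amplitude_uV <= 0) || any(base_center_freq_hz <= 0)) {
    abort_config("amplitudes and centre frequencies must be strictly positive")
  }
  if (fs_emg <= 2 * (max(base_center_freq_hz) + bandwidth_hz / 2)) {
    abort_config("fs_emg must exceed twice the highest shaping-band edge")
  }
  if (length(rom_base_amplitude_deg) == 1L) {
    rom_base_amplitude_deg <- rep(rom_base_amplitude_deg,
                                  length(rom_coordinates))
  }
  rom_base_amplitude_deg <- setNames(rom_base_amplitude_deg, rom_coordinates)
  eff <- setNames(numeric(length(rom_coordinates)), rom_coordinates)
  eff[names(rom_effects)] <- rom_effects
  if (lead_in_s < 1) {
    abort_config("`lead_in_s` must be at least 1 s so shifted marks never underflow")
  }

  sigma_u <- residual_log_sd *
    sqrt(subject_variance_share / (1 - subject_variance_share))

  structure(list(
    n_subjects = as.integer(n_subjects), weights_kg = weights_kg,
    n_boxes = as.integer(n_boxes), cadence_s = cadence_s,
    burst_duration_s = burst_duration_s, fs_emg = fs_emg,
    fs_mocap = fs_mocap, muscles = muscles,
    base_amplitude_uV = base_amplitude_uV,
    base_center_freq_hz = base_center_freq_hz, bandwidth_hz = bandwidth_hz,
    fatigue_amplitude_slope = fatigue_amplitude_slope,
    fatigue_spectral_slope = fatigue_spectral_slope,
    exo_amplitude_effect = exo_amplitude_effect,
    exo_fatigue_attenuation = exo_fatigue_attenuation,
    subject_variance_share = subject_variance_share,
    residual_log_sd = residual_log_sd, sigma_u = sigma_u,
    noise_floor_uV = noise_floor_uV, weight_gain_per_kg = weight_gain_per_kg,
    mech_delay_s = mech_delay_s, lead_in_s = lead_in_s,
    lead_out_s = lead_out_s, envelope_ramp_s = envelope_ramp_s,
    rom_coordinates = rom_coordinates,
    rom_base_amplitude_deg = rom_base_amplitude_deg,
    rom_effects = eff, rom_noise_sd_deg = rom_noise_sd_deg,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Deterministic sub-stream seed from the study seed and a set of tags.
mix_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) {
      codes <- utf8ToInt(p)
      sum(codes * seq_along(codes))
    } else {
      as.numeric(p)
    }
  }, numeric(1))
  val <- as.numeric(seed)
  for (p in parts) val <- (val * 48271 + p * 9349 + 1) %% 2147483647
  as.integer(val)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_exercise_args <- function(config, subject, condition, weight) {
  if (!inherits(config, "synth_config")) {
    abort_config("`config` must come from synth_config()")
  }
  if (!(is.numeric(subject) && length(subject) == 1L &&
        subject %in% seq_len(config$n_subjects))) {
    abort_input(sprintf("invalid subject index (1..%d)", config$n_subjects))
  }
  if (!condition %in% c("exo", "noexo")) {
    abort_input("`condition` must be \"exo\" or \"noexo\"")
  }
  if (!weight %in% config$weights_kg) {
    abort_input("`weight` is not one of config$weights_kg")
  }
}

#' Lognormal subject amplitude factor
#'
#' Deterministic in `(config$seed, subject)`; shared by the waveform and the
#' model-level generation paths.
#' @param config A [synth_config()].
#' @param subject Subject index.
#' @return Multiplicative factor `u_s > 0`.
#' @export
subject_factor <- function(config, subject) {
  z <- with_local_seed(mix_seed(config$seed, "subject", subject), rnorm(1))
  exp(config$sigma_u * z)
}

# Deterministic amplitude/frequency targets for one exercise: one row per
# (muscle, box), before the per-burst residual draw.
burst_targets <- function(config, subject, condition, weight) {
  u <- subject_factor(config, subject)
  ramp <- if (config$n_boxes > 1) {
    (seq_len(config$n_boxes) - 1) / (config$n_boxes - 1)
  } else {
    rep(0, config$n_boxes)
  }
  wgain <- 1 + config$weight_gain_per_kg * (weight - min(config$weights_kg))
  out <- do.call(rbind, lapply(config$muscles, function(m) {
    att <- if (condition == "exo") 1 - config$exo_fatigue_attenuation[[m]] else 1
    eff <- if (condition == "exo") config$exo_amplitude_effect[[m]] else 0
    data.frame(
      muscle = m, box = seq_len(config$n_boxes),
      amplitude_uV = config$base_amplitude_uV[[m]] * u *
        (1 + config$fatigue_amplitude_slope * ramp * att) * (1 + eff) * wgain,
      center_freq_hz = config$base_center_freq_hz[[m]] *
        (1 - config$fatigue_spectral_slope * ramp * att),
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "subject_factor") <- u
  out
}

burst_intervals <- function(config) {
  start <- config$lead_in_s + (seq_len(config$n_boxes) - 1) * config$cadence_s
  data.frame(box = seq_len(config$n_boxes),
             start_s = start, end_s = start + config$burst_duration_s)
}

# Raised-cosine-tapered (Tukey) envelope on n samples.
tukey_envelope <- function(n, ramp_n) {
  env <- rep(1, n)
  if (ramp_n > 0) {
    r <- seq_len(ramp_n)
    up <- 0.5 * (1 - cos(pi * r / ramp_n))
    env[r] <- up
    env[n + 1 - r] <- up
  }
  env
}

# Band-limited noise by phase-randomised frequency-domain synthesis: flat
# magnitude inside [center - bw/2, center + bw/2], random phases, zero
# outside. The spectrum is exactly band-limited and symmetric about the
# centre (no filter-tail skew), and the time series is asymptotically
# Gaussian as a sum of many independent-phase sinusoids.
band_noise <- function(n, fs, center_hz, bandwidth_hz) {
  lo <- max(center_hz - bandwidth_hz / 2, fs / n)
  hi <- min(center_hz + bandwidth_hz / 2, fs / 2 * 0.999)
  freqs <- (seq_len(n %/% 2)) * fs / n  # positive-frequency bins
  sel <- which(freqs >= lo & freqs <= hi)
  phases <- stats::runif(length(sel), 0, 2 * pi)
  spec <- complex(length.out = n)
  spec[sel + 1L] <- exp(1i * phases)
  # conjugate symmetry for a real series
  spec[n + 1L - sel] <- Conj(spec[sel + 1L])
  Re(fft(spec, inverse = TRUE)) / sqrt(n)
}

#' Generate one exercise of synthetic surface EMG
#'
#' Synthesises the 4-channel EMG of one `(subject, condition, weight)`
#' exercise: `n_boxes` noise bursts per muscle on a white baseline, with the
#' amplitude/frequency structure described in [synth_config()]. Each burst is
#' rescaled so its RMS over the burst support equals the realised per-burst
#' target, which is recorded in the ground truth.
#'
#' @param config A [synth_config()].
#' @param subject Subject index in `1..n_subjects`.
#' @param condition `"exo"` or `"noexo"`.
#' @param weight One of `config$weights_kg`.
#' @return A list with components `recording` (an `emg_recording`) and
#'   `truth` (class `emg_ground_truth`: burst intervals, per-burst targets and
#'   realised amplitudes, and the subject factor).
#' @export
generate_emg <- function(config, subject, condition, weight) {
  check_exercise_args(config, subject, condition, weight)
  targets <- burst_targets(config, subject, condition, weight)
  iv <- burst_intervals(config)
  fs <- config$fs_emg
  dur <- config$lead_in_s + (config$n_boxes - 1) * config$cadence_s +
    config$burst_duration_s + config$lead_out_s
  n <- round(dur * fs)
  nb <- round(config$burst_duration_s * fs)
  env <- tukey_envelope(nb, round(config$envelope_ramp_s * fs))

  ex_seed <- mix_seed(config$seed, "emg", subject, condition, weight)
  samples <- with_local_seed(ex_seed, {
    mat <- matrix(0, nrow = n, ncol = length(config$muscles))
    realized <- numeric(nrow(targets))
    for (r in seq_len(nrow(targets))) {
      m_idx <- match(targets$muscle[r], config$muscles)
      b <- targets$box[r]
      e <- exp(rnorm(1, 0, config$residual_log_sd))
      realized[r] <- targets$amplitude_uV[r] * e
      w <- band_noise(nb, fs, targets$center_freq_hz[r], config$bandwidth_hz)
      seg <- env * w
      seg <- seg * (realized[r] / sqrt(mean(seg^2)))
      i0 <- round(iv$start_s[b] * fs)
      mat[(i0 + 1L):(i0 + nb), m_idx] <- mat[(i0 + 1L):(i0 + nb), m_idx] + seg
    }
    if (config$noise_floor_uV > 0) {
      mat <- mat + matrix(rnorm(n * ncol(mat), 0, config$noise_floor_uV),
                          nrow = n)
    }
    attr(mat, "realized") <- realized
    mat
  })
  realized <- attr(samples, "realized")
  attr(samples, "realized") <- NULL
  targets$realized_uV <- realized

  rec <- new_emg_recording(samples, fs, config$muscles,
                           meta = list(subject = subject,
                                       condition = condition,
                                       weight_kg = weight,
                                       exercise_id = exercise_id(subject,
                                                                 condition,
                                                                 weight)))
  truth <- structure(list(intervals = iv, targets = targets,
                          subject_factor = attr(targets, "subject_factor")),
                     class = "emg_ground_truth")
  list(recording = rec, truth = truth)
}

exercise_id <- function(subject, condition, weight) {
  sprintf("s%02d_%s_%gkg", subject, condition, weight)
}

#' Generate one exercise of synthetic joint-angle motion
#'
#' One excursion per lift for each joint coordinate, with a half-cosine bump
#' spanning the mechanical lift (from `mech_delay_s` after the EMG burst onset
#' to the burst end). Excursion amplitude grows with pallet row (lower boxes
#' demand deeper flexion) and, under the exoskeleton, is scaled by
#' `1 + rom_effects[coordinate]`. Coarse segment marks are the mechanical
#' lift intervals quantised to the motion sampling grid.
#'
#' @inheritParams generate_emg
#' @return A list with `recording` (a `motion_recording`) and `marks` (coarse
#'   marks data frame: `box`, `start_s`, `end_s`).
#' @export
generate_mocap <- function(config, subject, condition, weight) {
  check_exercise_args(config, subject, condition, weight)
  fs <- config$fs_mocap
  iv <- burst_intervals(config)
  dur <- config$lead_in_s + (config$n_boxes - 1) * config$cadence_s +
    config$burst_duration_s + config$lead_out_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  row_gain <- c(0.85, 0.95, 1.05, 1.15)

  mech_start <- iv$start_s + config$mech_delay_s
  mech_end <- iv$end_s
  ex_seed <- mix_seed(config$seed, "mocap", subject, condition, weight)
  angles <- with_local_seed(ex_seed, {
    mat <- matrix(0, nrow = n, ncol = length(config$rom_coordinates))
    for (ci in seq_along(config$rom_coordinates)) {
      coord <- config$rom_coordinates[ci]
      amp0 <- config$rom_base_amplitude_deg[[coord]]
      scale <- if (condition == "exo") 1 + config$rom_effects[[coord]] else 1
      for (b in seq_len(config$n_boxes)) {
        gi <- row_gain[pmin(ceiling(b / 4), length(row_gain))]
        sel <- t >= mech_start[b] & t <= mech_end[b]
        u <- (t[sel] - mech_start[b]) / (mech_end[b] - mech_start[b])
        mat[sel, ci] <- amp0 * gi * scale * sin(pi * u)^2
      }
      mat[, ci] <- mat[, ci] + rnorm(n, 0, config$rom_noise_sd_deg)
    }
    mat
  })

  rec <- new_motion_recording(angles, fs, config$rom_coordinates,
                              meta = list(subject = subject,
                                          condition = condition,
                                          weight_kg = weight,
                                          exercise_id = exercise_id(subject,
                                                                    condition,
                                                                    weight)))
  q <- function(x) round(x * fs) / fs
  marks <- data.frame(box = iv$box, start_s = q(mech_start), end_s = q(mech_end))
  list(recording = rec, marks = marks)
}

#' Model-level fast path: per-burst feature values without waveforms
#'
#' Draws the per-(subject, condition, weight, box) RMS amplitudes of one
#' muscle directly from the generator's amplitude model (the same lognormal
#' subject factor, fatigue/condition/weight structure and per-burst residual
#' that [generate_emg()] realises as waveforms). Intended for simulation
#' studies of the mixed model, where synthesising and re-measuring full-rate
#' waveforms adds nothing but run time.
#'
#' @param config A [synth_config()].
#' @param muscle One of `config$muscles`.
#' @return A model frame: `user`, `exo` (`"noexo"`/`"exo"`), `weight_kg`,
#'   `box`, `vrms_uV`.
#' @export
simulate_feature_frame <- function(config, muscle = config$muscles[1]) {
  if (!muscle %in% config$muscles) abort_input("unknown muscle label")
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    for (cond in c("noexo", "exo")) {
      for (w in config$weights_kg) {
        tg <- burst_targets(config, s, cond, w)
        tg <- tg[tg$muscle == muscle, ]
        e <- with_local_seed(
          mix_seed(config$seed, "frame", s, cond, w, muscle),
          rnorm(nrow(tg), 0, config$residual_log_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          user = s, exo = cond, weight_kg = w, box = tg$box,
          vrms_uV = tg$amplitude_uV * exp(e))
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a full synthetic study to disk
#'
#' Generates every `(subject, condition, weight)` exercise of the configured
#' study and writes the CSV dialects used by the pipeline: per-exercise EMG,
#' joint angles, coarse marks and ground truth, plus a study manifest.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    for (cond in c("noexo", "exo")) {
      for (w in config$weights_kg) {
        id <- exercise_id(s, cond, w)
        emg <- generate_emg(config, s, cond, w)
        moc <- generate_mocap(config, s, cond, w)
        paths <- list(emg = file.path(dir, paste0(id, "_emg.csv")),
                      mocap = file.path(dir, paste0(id, "_mocap.csv")),
                      marks = file.path(dir, paste0(id, "_marks.csv")),
                      truth = file.path(dir, paste0(id, "_truth.csv")))
        write_emg_csv(emg$recording, paths$emg)
        write_mocap_csv(moc$recording, paths$mocap)
        write_marks_csv(cbind(exercise_id = id, moc$marks, flag = ""),
                        paths$marks)
        write_ground_truth(emg$truth, paths$truth)
        rows[[id]] <- data.frame(
          subject = s, condition = cond, weight_kg = w, exercise_id = id,
          emg_path = paths$emg, mocap_path = paths$mocap,
          marks_path = paths$marks, truth_path = paths$truth,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d subjects x {exo, noexo} x %s kg; %d boxes @ %.1f s\n",
    x$n_subjects, paste(x$weights_kg, collapse = "/"), x$n_boxes, x$cadence_s))
  cat(sprintf("  EMG %g Hz (%s), motion %g Hz; seed %d\n",
              x$fs_emg, paste(x$muscles, collapse = ", "), x$fs_mocap, x$seed))
  invisible(x)
}
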