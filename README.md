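# exolift

Surface-EMG and motion analysis for assessing passive lumbar exoskeletons
in repetitive lifting tasks.

Occupational studies test such devices by instrumenting workers with
surface electromyography (sEMG) on the trunk and leg muscles and inertial
motion capture on the joints, then comparing a standardised box-lifting
protocol performed with and without the exoskeleton. `exolift` implements
the complete analysis for a depalletizing protocol — 16 boxes per exercise
at a 6-s cadence, three box weights, four muscles at 2000 Hz, joint angles
at 100 Hz — together with a synthetic multi-subject generator with
per-stage ground truth, so every stage is testable end to end.

The pipeline:

1. **Preprocess** — zero-phase Butterworth band-pass, 20–200 Hz, order 10
   (`bandpass_filter()`).
2. **Segment** — motion-derived lift marks shifted 1 s earlier (muscle
   activation precedes movement), then refined on a combined
   channel-normalised RMS intensity trace with an 85%/15% threshold rule
   (`shift_marks()`, `combined_intensity()`, `refine_marks()`).
3. **Features** per lift and muscle (`extract_features()`):
   RMS amplitude `VRMS`; zero-crossing rate `TZC` (%); spectrogram mean and
   median frequency `FMN`, `FMD` (0.5-s windows, 1024 bins to 1 kHz); the
   Dimitrov spectral fatigue index
   `FI = Σ f⁻¹·PSD(f) / Σ f⁵·PSD(f)` over 20–200 Hz, and its normalised
   logarithm `log(FIn) = log(FI / FI_min)` per exercise and muscle.
4. **Stats** — for each variable and muscle, the linear mixed model
   `y ~ exo * box + weight + (1 | user)` (REML, lme4), uniformly-averaged
   adjusted condition means, the percent change
   `(mean_exo − mean_noexo)/mean_noexo × 100` with a delta-method 95%
   interval, Holm-adjusted p-values, and the intra-class correlation that
   justifies the subject random intercept (`run_effects()`).
5. **Range of motion** — P5…P95 percentiles per joint coordinate,
   `PRoM = P95 − P5`, paired t-tests between conditions (`rom_summary()`).

`run_pipeline()` drives all of it from a manifest of exercise CSVs and
writes tidy result tables plus a run log; `inst/cli/exolift.R` is a thin
command-line wrapper (`simulate`, `run`).

## Worked example

Simulate a 4-subject study and run the full analysis:

```r
library(exolift)

cfg <- synth_config(n_subjects = 4, seed = 42)
dir <- file.path(tempdir(), "study")
simulate_study(cfg, dir)

res <- run_pipeline(file.path(dir, "manifest.csv"), pipeline_config(),
                    file.path(tempdir(), "results"))

subset(res$effects$effects, variable %in% c("vrms_uV", "log_fin"),
       select = c(variable, muscle, percent, ci_halfwidth, p_holm, stars))
```

```
   variable         muscle percent ci_halfwidth   p_holm stars
1   vrms_uV erector_spinae   -9.71         2.75 5.21e-11  ****
2   vrms_uV        gluteus   -7.39         2.89 2.23e-06  ****
3   vrms_uV     quadriceps   -6.50         2.71 4.52e-06  ****
4   vrms_uV semitendinosus  -17.67         2.93 7.51e-30  ****
17  log_fin erector_spinae  -23.09         3.21 8.31e-37  ****
18  log_fin        gluteus  -16.91         2.92 7.67e-28  ****
19  log_fin     quadriceps   -1.00         2.33 4.03e-01
20  log_fin semitendinosus  -21.91         2.08 1.23e-75  ****
```

Negative `percent` means a reduction with the exoskeleton. The recovered
VRMS reductions track the generator's configured amplitude effects
(−8/−5/−4/−14% by muscle) plus the contribution of its slowed fatigue
drift; `log(FIn)` drops for the three assisted muscles (less fatigue
build-up) and is null for the quadriceps, whose fatigue attenuation is
configured to zero.

```r
subset(res$rom$comparison, statistic == "PRoM" &
       coordinate %in% c("lumbar_rotation", "lumbar_flexion_extension"))
```

```
                 coordinate statistic percent ci_halfwidth        p
13 lumbar_flexion_extension      PRoM   -2.93        0.264 4.97e-05
15          lumbar_rotation      PRoM  -37.88        0.363 6.01e-08
```

The configured range-of-motion restrictions (−3% lumbar
flexion/extension, −39% lumbar rotation) are recovered from the generated
joint-angle traces.

See `vignettes/exolift-methods.Rmd` for the model, the generator's
assumptions, and every numerical convention.

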