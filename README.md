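# mewdssf — structure–function analysis of photoreceptor recovery in MEWDS

Multiple evanescent white dot syndrome (MEWDS) is a self-limiting inflammatory
retinopathy in which the photoreceptor outer segments are transiently
disrupted and then recover over weeks. This package implements, as a tested
and reusable R pipeline, the quantitative structure–function analysis of that
recovery:

* **PRR mapping** — the *photoreceptor reflectivity ratio* per OCT A-scan:
  the mean back-reflected intensity of the outer-segment band spanning
  **20 to 6 pixels above the RPE**, normalized by a reference (vitreous) band
  so that media opacities cancel, assembled into en-face PRR maps.
* **Microperimetry analytics** — the 68-stimulus rectilinear grid covering
  the central 10°, 4-2 staircase threshold simulation, average and foveal
  retinal threshold sensitivity (RTS, dB), and fixation statistics: the
  bivariate contour ellipse area
  `BCEA_P = −2 ln(1−P) · π · σx · σy · √(1−ρ²)` at P = 63% and 95%, and the
  P1/P2 (2°/4° circle) stability classification.
* **Co-registration** — least-squares 2-D affine mapping of microperimetry
  stimulus coordinates into the OCT en-face frame, and the joined
  (patient, eye, visit, location) structure–function table.
* **Hierarchical structure–function model** — the Hood–Kardon convention:
  sensitivities are converted to the linear scale `S_lin = 10^(dB/10)` and
  PRR is regressed on `S_lin` in a linear mixed model with a random intercept
  per patient, `PRR = β₀ + β₁·S_lin`; viewed on the dB scale this
  relationship is asymptotic (→ β₀) for deep sensitivity losses.
* **Longitudinal models** — mixed-effects recovery trajectories
  `RTS ~ day × baseline BCVA` (random intercept per eye), group comparisons,
  and the location-level centrifugal-gradient model `RTS ~ day × region`.
* **Synthetic cohort generator** — first-class, tested code that simulates
  cohorts of eyes (lesioned sensitivity fields with region-specific recovery
  time constants, foveal granularity, fixation dispersion coupled to foveal
  deficit, BCVA coupled to foveal sensitivity, layered OCT phantom volumes
  carrying the forward structure–function model), so every stage of the
  pipeline is testable without patient data.

## Worked example

```r
library(mewdssf)

cfg <- cohort_config()                    # the default study conditions
coh <- generate_cohort(cfg, seed = 17)
nrow(coh$eyes)                            # 16 eyes (13 patients + bilaterals)

# examine one eye at presentation
ex <- examine_eye(coh$fields[[1]], build_grid(), visit_day = 0, cfg, seed = 1)
average_rts(ex)                           # 19.0 dB
foveal_rts(ex)                            # 21.5 dB

# render its OCT cube, map the PRR, join structure and function
vol <- render_oct_volume(coh$fields[[1]], 0, cropped_geometry(), cfg, seed = 1)
map <- build_prr_map(vol, detect_rpe(vol))
tab <- build_structure_function_table(list(ex), list(map))
nrow(tab)                                 # 64 of 68 stimuli inside the footprint
```

Running the whole workflow (`analysis/01…04` scripts, seed 17) prints, among
other things:

```
recovery slope: 0.0589 dB/day (p = 2.7e-17)
slope x baseline BCVA interaction: 0.0866 dB/day per LogMAR (p = 0.032)
early-window (<= 30 d) recovery slopes by region, dB/day:
      central  extramacular peripapillary
       0.2248        0.1765        0.1140
```

i.e. sensitivity recovers on the order of 0.06 dB/day on average, faster in
eyes presenting with worse acuity, and with a centrifugal gradient — fastest
centrally, slowest around the disc.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
cohort and write their outputs under `results/run/`:

1. `01_simulate_and_map.R` — cohort, exams, OCT phantoms, PRR maps, joined
   structure–function table.
2. `02_baseline_function.R` — baseline RTS/fixation summaries, granularity
   contrasts, exploratory correlations.
3. `03_structure_function.R` — hierarchical Hood–Kardon fit, eccentricity
   interaction, nesting robustness.
4. `04_longitudinal_recovery.R` — recovery trajectory and the
   centrifugal-gradient analysis.

## Package layout

`R/` — generator (`config.R`, `field.R`, `cohort.R`), OCT and PRR modules
(`oct.R`, `prr.R`), microperimetry (`microperimetry.R`), registration
(`registration.R`), statistical models (`models.R`), and the pipeline
composition (`pipeline.R`). `vignettes/mewds-structure-function.Rmd`
describes the model, its assumptions, and the design decisions.
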