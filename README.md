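# paoxim

Photoacoustic oximetry analysis for real-time monitoring of tumor blood
oxygenation during photodynamic therapy (PDT).

Ultrasound-guided photoacoustic imaging (US-PAI) acquires interleaved
frames at 750 nm and 850 nm, on opposite sides of the ~800 nm hemoglobin
isosbestic point. Because deoxyhemoglobin (HbD) absorbs more strongly at
750 nm and oxyhemoglobin (HbO) at 850 nm, each pixel's two amplitudes can
be unmixed into chromophore contributions, yielding maps of oxygen
saturation and total hemoglobin during treatment. PDT consumes tissue
oxygen as the light-activated photosensitizer produces reactive oxygen
species, so the tumor StO₂ trajectory — sharp initial drop, transient
vasodilation rebound, steady decline to a trough, heterogeneous
reoxygenation — carries dosimetric information about how much photodynamic
damage was actually delivered, and where.

`paoxim` is for researchers analyzing such recordings (or prototyping
analysis methods for them): it implements the full pipeline from raw
two-wavelength frame stacks to kinetic summaries and spatial change maps,
together with a synthetic tumor-phantom generator so every stage can be
validated against ground truth without animal data.

## The model

Per pixel, the measured amplitudes **m** = (m₇₅₀, m₈₅₀) follow
**m** ≈ E **c**, where E holds the molar extinction coefficients
ε_HbO(λ), ε_HbD(λ) and **c** = (c_HbO, c_HbD) ≥ 0. The package solves the
non-negative least squares problem

  min‖E **c** − **m**‖₂ s.t. **c** ≥ 0

in closed form (the two-unknown active sets can be enumerated), then
reports

- HbT = c_HbO + c_HbD (arbitrary units — photoacoustic amplitudes are
  uncalibrated, so only extinction ratios matter),
- StO₂ = 100 · c_HbO / HbT (%), which is invariant to overall system gain.

Pixels whose HbT falls below a per-recording noise floor — the mean HbT of
two 20 × 20 px patches in the top corners, pooled over all frames — are
masked. ROI kinetics then average StO₂ over valid tumor pixels per frame,
median-filter the trace (order 15, truncated windows at the edges), scale
it so the 5-min pre-light baseline averages exactly 100%, and derive:

- the **depletion rate**: mean moving-window least-squares slope
  (normalized %/min) over the first 5 min of irradiation,
- the **end of active PDT**: where the normalized trace stops decreasing
  during light (trough of the trace, or light-off for a monotone decline),
- **ΔStO₂ maps**: element-wise StO₂ differences between milestones
  (pre-light → end of active PDT: deoxygenation; end of active PDT → end
  of monitoring: reoxygenation), with a 3 × 3 median filter for display,
- group comparisons of depletion rates by one-way ANOVA with Tukey HSD,
- the Severinghaus dissociation curve
  S = 100/(23400/(p³ + 150 p) + 1) for pO₂ ↔ SO₂ conversion.

## Worked example

Simulate a high-fluence-rate (400 mW/cm², 360 J) treatment phantom and run
the full analysis:

```r
library(paoxim)

light_dose(100, 15 * 60)   # LFR protocol: 90  (J)
light_dose(400, 15 * 60)   # HFR protocol: 360 (J)
severinghaus_so2(10)       # 9.65251 (% SO2 at 10 mmHg, the hypoxia landmark)

fx  <- make_fixture("HFR", seed = 1)           # 128x128 px, 30 min at 4 s/frame
res <- analyze_stack(fx$stack, fx$roi, fx$spec$timeline)
round(res$summary, 3)
#>          baseline_sto2        noise_threshold         depletion_rate
#>                 58.810                  0.014                 -7.079
#>           t_active_end reox_positive_fraction              rate_left
#>                720.000                  0.553                 -7.088
#>             rate_right
#>                 -7.069
```

Read: resting tumor StO₂ averaged 58.8%; the corner noise floor was 0.014
HbT units; StO₂ fell at 7.1 normalized %/min over the first 5 min of
light; active PDT ended 720 s into the recording (7 min into the light
dose — the phantom's programmed photobleaching trough, at the 12-min mark
of the session); 55.3% of tumor pixels reoxygenated afterwards (the
phantom programs 54.7%, rim-concentrated); and the two lateral tumor
halves depleted at matching rates, as expected for a symmetric dose.

Group statistics on per-subject depletion rates:

```r
set.seed(21)
rates <- data.frame(group = rep(c("HFR", "LFR", "light_only"), each = 5),
                    rate  = c(rnorm(5, -20, 2), rnorm(5, -2, 2), rnorm(5, 0, 2)))
compare_group_rates(rates)
#>             pair  diff   lwr   upr    p_adj significant
#> 1        LFR-HFR 15.60 11.71 19.50 4.88e-07        TRUE
#> 2 light_only-HFR 17.87 13.98 21.77 1.08e-07        TRUE
#> 3 light_only-LFR  2.27 -1.62  6.17 3.01e-01       FALSE
```

File-based workflows use `write_frame_stack()`/`read_frame_stack()`
(multi-page TIFF + JSON sidecar), `read_roi_png()`, and `run_pipeline()`
with a YAML configuration, which writes the trace CSV, milestone JSON,
pseudocolor ΔStO₂ PNGs and a summary JSON.

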