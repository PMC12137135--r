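---
title: "Methods: photoacoustic oximetry analysis for PDT monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photoacoustic oximetry analysis for PDT monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paoxim)
```

This vignette documents the models, parameter choices and numerical
conventions behind `paoxim`, in the spirit of a methods section: what each
stage assumes, which knobs matter, and what validation on the synthetic
phantom does and does not demonstrate about real recordings.

## Spectral unmixing

Two-wavelength photoacoustic oximetry assumes the per-pixel amplitude is a
non-negative linear mixture of oxy- and deoxyhemoglobin absorption,

$$m_\lambda = g_\lambda\,(\varepsilon_{HbO}(\lambda)\,c_{HbO} +
\varepsilon_{HbD}(\lambda)\,c_{HbD}) + \epsilon_\lambda,$$

with channel gains $g_\lambda$ and noise $\epsilon_\lambda$ of either
sign. The package ships the standard tabulated hemoglobin molar extinction
coefficients at 750 and 850 nm (`hb_extinction()`, cm⁻¹M⁻¹). Three
assumptions matter:

- **Sign structure.** $\varepsilon_{HbD} > \varepsilon_{HbO}$ at 750 nm
  and the reverse at 850 nm; the constructor enforces this, because it is
  what makes the 2×2 system well conditioned.
- **Equal (or folded-in) channel gains.** Whether amplitudes were
  gain/fluence-compensated per wavelength before unmixing is usually not
  reported for clinical scanners; the pipeline assumes $g_{750} = g_{850}$
  or that the ratio is absorbed into the phantom's `gain` parameter.
  Because StO₂ is a ratio, a *common* gain cancels exactly
  (`unmix_pixel(k·m) = k·unmix_pixel(m)`), but a *differential* gain would
  bias saturation — the one calibration the method genuinely needs.
- **No fluence correction, two chromophores only.** Depth-dependent
  spectral coloring and additional absorbers (e.g. the photosensitizer)
  are out of scope.

The constrained problem $\min\|Ec-m\|_2,\ c\ge 0$ is solved in closed
form: the unconstrained 2×2 solution if feasible, otherwise the better of
the two single-chromophore projections clamped at zero — an exact
enumeration of the KKT active sets for two unknowns (and for any number of
wavelengths ≥ 2, since the design always has two columns). Determinism and
speed were the reasons to avoid an iterative solver; the test suite checks
the solution against a dense grid search over $c \in [0, c_{max}]^2$ at
$10^{-3} c_{max}$ resolution, using the Hessian bound
$\lambda_{max}\Delta^2$ for the admissible discretization gap.

Pixels with HbT = 0 have undefined saturation; they are stored as 0 with
`mask = FALSE`. The mask, not the zero, is the authoritative validity
signal — downstream code must never read a masked 0 as true 0%
saturation. One noise threshold is computed **per recording** (mean HbT of
the two 20 × 20 px top-corner patches pooled across all frames); image
row 1 is the shallowest, transducer-proximal row, so these patches sample
couplant/water above the tissue surface. Thresholding is idempotent.

## ROI kinetics

The tumor ROI is annotated on the co-registered B-mode image. Per frame,
`roi_mean_trace()` averages StO₂ over pixels that are inside the ROI *and*
above the noise floor ("excluding zero values"): masked pixels are
missing, not zero, so a frame that is half masked is not diluted toward
0%. Frames with no valid ROI pixel propagate as `NA` and are skipped, not
imputed, by every later stage.

Processing order is **filter, then normalize**:

1. `median_filter_trace()`, window 15 samples (≈ 1 min at the 4 s frame
   period). Edge policy: windows *truncate* at the series ends. The
   conventional zero-padded running median would drag the first half
   window toward zero and bias the 100% baseline downward at the recording
   start, so the truncating variant is deliberate.
2. `normalize_trace()` multiplies by 100/mean(baseline), where the
   baseline is `[t_baseline_start, t_light_on)`. The normalized baseline
   then averages exactly 100 (to floating-point), which the tests assert
   at 10⁻⁹ relative tolerance. The study protocol contains both an earlier
   3-D scan and a 5-min 2-D pre-light acquisition; the package defaults to
   the 5-min 2-D pre-light window (it is the one sampled at the trace's
   own frame rate) and exposes the window through the timeline object.

**Depletion rate.** `moving_slope()` fits an ordinary least-squares slope
of normalized StO₂ against time (minutes) in a centered window, truncated
at the edges; `mean_depletion_rate()` averages it over the first 5 min of
light. The window length is not specified by common practice; the default
of 15 samples matches the median-filter order so both operate on the same
smoothing scale, and it is configurable. On an affine trace the estimator
is exact at every index, including the truncated edges.

**End of active PDT.** Active PDT ends when oxygen consumption stops
depleting the trace. The default `argmin` rule takes the global minimum of
the normalized channel over the light interval, with one refinement that
deserves explanation. A sliding median maps any V-shaped trough onto a run
of *exactly tied* output samples (consecutive windows share the same
median sample), so "earliest minimum" would systematically report the
plateau's first sample — up to half a filter window early. The rule
therefore returns the **center of the tied run**; if the run reaches the
last sample of the light interval, the trace was still declining at
light-off and `t_light_off` is returned (active PDT lasted through the
light dose), which also covers the strictly monotone case. Detection is
invariant to positive affine rescaling of the trace. A `plateau` rule
(first time after which the trace never drops more than `delta` below its
running minimum for `run` samples) is provided as a sensitivity check,
since the underlying endpoint definition is qualitative.

**Group statistics.** Per-subject rates are compared by ordinary one-way
ANOVA with Tukey HSD (`stats::aov` + `stats::TukeyHSD`), significance at
p < 0.05; the tests verify the family-wise error rate by simulation under
the null.

**Severinghaus curve.** $S = 100\,(23400/(p^3 + 150p) + 1)^{-1}$,
strictly increasing; the inverse solves the monotone cubic by
root-finding and round-trips to 10⁻⁶ mmHg. At 10 mmHg the curve gives
≈ 10% SO₂, the conventional hypoxia landmark used when comparing low-StO₂
regions with hypoxia staining.

## Difference maps and lateral splits

`delta_sto2()` subtracts milestone StO₂ maps on the **joint** valid mask;
pixels valid at only one milestone are excluded rather than treated as a
change from/to 0, which would fabricate ±100% swings at the noise floor.
Negative values mean deoxygenation for the pre-light → end-of-active-PDT
map, positive values reoxygenation for the end-of-active-PDT →
end-of-monitoring map. The 3 × 3 display median (nearest-edge replication)
is applied after the subtraction and only for display; no statistic in the
package consumes filtered maps.

For asymmetric dosing, `split_roi_lateral()` divides the ROI at its own
lateral centroid column (left: strictly below; right: at or above), so the
split tracks the tumor rather than the image frame; how published figures
delineate halves (ROI centroid vs. image midline) is typically unstated,
so a `midline` option is provided. The halves always partition the ROI
exactly.

## The synthetic phantom

No public dataset accompanies this class of experiment, so the package
includes a generator whose defaults *are* the study conditions: 128 × 128
px at 0.1 mm, elliptical tumor cross-section, 5-min baseline, 15-min
light, ~10-min follow-up at a 4 s frame period, treatment fluence rates
summed over four fibers — 100 mW/cm² (LFR, 90 J), 400 mW/cm² (HFR, 360 J),
light-only (HFR irradiance, no photosensitizer), and an asymmetric layout
(two in-plane fibers at 100, left 150, right 50 mW/cm², a linear lateral
gradient across the tumor). A note on the frame period: the nominal
acquisition arithmetic (20 Hz, 20-frame averages, two wavelengths)
suggests ~2 s per pair, while such recordings are reported at roughly 4 s
effective spacing; the simulator uses 4 s and the discrepancy does not
affect any conclusion drawn here.

Saturation follows a phenomenological per-pixel update (explicit Euler,
clipped to [0, 100]):

$$\Delta S = \Delta t\,[-k_c\,\Phi(x)\,P(t)\,S/100 + v(t)(S_0(x)-S)
  - k_s\,W(x,t)\,S + r(x)\,k_r\,(S_0(x)-S)\,\mathbf{1}(t>t^*)]$$

- $P(t) = \exp(-k_b\bar\Phi t)$: a global photosensitizer pool bleached by
  the mean tumor irradiance, clamped to 0 below `ps_floor` (exhaustion).
  The trough time $t^* = t_{on} + \ln(1/p_{floor})/(k_b\bar\Phi)$, capped
  at light-off, is therefore *programmed*: ~7 min into the light dose for
  HFR, beyond light-off for LFR.
- $v(t)$: a Gaussian vasodilation bump (default peak at minute 7 of the
  recording, ≈ 2 min into light) restoring a fraction of the saturation
  deficit per minute — the transient reflow that briefly reverses the
  early decline.
- $W = 1-\exp(-D/D_0)$ with $D = \int\Phi P\,dt$: vascular shutdown
  driven by accumulated local photodynamic dose; it persists after
  light-off, giving non-recovering tissue its continued slow decline.
- $r(x)$: the programmed recovering region, a rim band (default 0.6 mm)
  plus one interior patch (default 10% of the interior) — post-trough
  reoxygenation concentrated at the tumor rim. HbT is modulated ±20% by
  $v$ and $W$.

All vascular responses are reactions to photodynamic insult, so they are
gated on photosensitizer presence: the light-only phantom (`k_consume =
0`) is *exactly* static, which gives the null group its ≈ 0 depletion
rate. Kinetic coefficients (`k_consume = 0.05 %·cm²·mW⁻¹·min⁻¹`,
`k_bleach = ln 4/2800 cm²·mW⁻¹·min⁻¹`, `ps_floor = 0.25`,
`k_shutdown = 0.02 min⁻¹`, `D₀ = 500 mW·min·cm⁻²`, recovery rate
0.2 min⁻¹) were chosen once so the HFR bulk trace qualitatively reproduces
the canonical treatment trajectory — a drop within the first minute, a
secondary peak near minute 7 of the session, a distinct trough near minute
12, partial rim reoxygenation — and so the trough is as sharp as observed
traces show it (the exhaustion cutoff at 25% availability creates the
kink); a mushier trough would be ill-posed for *any* endpoint detector.

One modeling consequence is worth stating. With a **global**
photosensitizer pool, raising a *single* side fiber shortens the active
interval everywhere, which can leave weakly-illuminated pixels with
*shallower* troughs — so "more light ⇒ deeper trough everywhere" holds
only for dose changes that preserve the relative illumination pattern
(e.g. scaling all fibers), and that is how the property is tested. This is
not a defect of the model: high-fluence-rate PDT is self-limiting, and
redistributed light genuinely can protect distant tissue by exhausting the
shared photosensitizer sooner.

Measurement rendering is the forward model of the unmixer: per wavelength,
signal = gain × (εc) plus additive Gaussian noise with SD equal to
`noise_sd` (default 2%) of the mean tumor signal, background noise-only.
Additive channel noise before unmixing is sufficient to exercise the
noise-floor masking and the non-negativity clamping; there is no speckle,
motion, depth-dependent fluence, or wavelength-dependent gain drift. All
randomness flows from the single spec seed; identical spec + seed is
bit-identical.

**What phantom validation shows — and does not.** Passing recovery tests
(rate ordering HFR < LFR < light-only, endpoint within one frame of the
programmed trough, reoxygenated-area fraction within 5 points of the
programmed fraction, left/right lateralization under asymmetric dosing)
demonstrates that the *pipeline* is correct and adequately conditioned at
realistic noise. It does not validate the biology: real tumors add motion,
speckle, depth-dependent fluence, vascular heterogeneity beyond a rim
band, and inter-animal kinetic variability far exceeding the phantom's.
Truth milestones are defined on the noiseless dynamics (the trough is the
frame-grid argmin of the true ROI-mean trace over the light interval, with
the analytic exhaustion time kept separately), so recovery comparisons
never peek at the analysis path.

## Numerical conventions and degenerate inputs

- Images are row-major with row 1 shallowest; "top corners" are rows
  1–20 and the first/last 20 columns.
- Unmixing requires finite measurements; `m = (0,0)` yields `(0,0)` and a
  masked pixel, not an error.
- The integrator refuses a frame period that violates its stability bound
  and suggests the admissible one.
- Even median-filter orders, slope windows < 2, empty ROIs, non-positive
  baselines, groups of size < 2, and pO₂ ≤ 0 all raise immediate,
  specific errors rather than propagating silently.
- Degenerate one-column ROIs split into one empty half with a warning.
- Frame stacks serialize as wavelength-interleaved multi-page 32-bit TIFF
  with a JSON sidecar carrying times, wavelengths, pixel spacing and the
  affine intensity scale (TIFF float storage is reliable only in [0, 1]);
  round-trip is exact to float32 precision.

## Problem sizes used in validation

Unit tests run on 48 × 48 phantoms with a shortened 7-min protocol and
proportionally faster photobleaching; the acceptance-style recovery tests
run the full study conditions (128 × 128, 30-min protocol, 4 s frames)
with 20 seeds per treatment group, and the unmixing oracle uses 1000
random measurement pairs against a 1001 × 1001 grid. These sizes make the
whole suite a few minutes of single-core compute while keeping every
recovery claim at the conditions the fixtures emulate.

## Known limitations

- Two chromophores, two wavelengths: no photosensitizer unmixing, no
  fluence correction, no >2-λ spectra beyond the generic solver path.
- No motion registration between frames or between pre/post 3-D scans.
- HbT is relative; absolute hemoglobin concentration requires calibration
  the modality does not provide.
- The phantom's kinetics are phenomenological, not a photochemical dose
  model; its parameters are plausible, not fitted to data.
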