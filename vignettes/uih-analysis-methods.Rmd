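---
title: "Models and methods behind uihkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uihkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uihkit)
```

`uihkit` implements the analysis stack of ultrasound-induced hypothermia and
hypometabolism (UIH) experiments: thermal-video BAT tracking, windowed
physiological endpoints, a closed-loop body-temperature controller, fiber
photometry statistics, histology positivity quantification, and rule-based
snRNA-seq annotation, together with seeded synthetic-data generators that
provide ground truth for every stage. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic tests
do and do not demonstrate about real data.

## The thermoregulatory plant

The simulated mouse is deliberately the simplest model that shows the
dip-and-spontaneous-recovery shape of a torpor-like bout:

$$\frac{dT}{dt} = -k_\mathrm{loss}\,(T - T_\mathrm{amb}) + k_\mathrm{therm}\,H(t),
\qquad
\frac{dH}{dt} = \frac{H_0 - H}{\tau_\mathrm{recovery}},$$

first-order Newtonian cooling plus a thermogenic drive $H \in [0,1]$. Each
ultrasound train decrements $H$ instantaneously; the decrement scales
linearly with acoustic pressure above a 0.8 MPa threshold (trains below the
threshold do nothing) and saturates at a floor `h_floor`, so repeated trains
cannot suppress thermogenesis below a physiological minimum. The plant is an
emulation target for the package's pipelines, not a mechanistic claim about
POA circuitry.

Default parameters (all settable through `plant_params()`):

| parameter | default | unit | rationale |
|---|---|---|---|
| `t_amb` | 22 | °C | room-temperature housing |
| `k_loss` | 0.035 | min⁻¹ | ~29 min thermal time constant of a mouse |
| `k_therm` | 0.6475 | °C·min⁻¹ | sets the equilibrium T = 36.8 °C at H₀ |
| `h0` | 0.8 | – | baseline drive, leaves headroom for cold stress |
| `suppression_per_train` | 0.45 | – | one full train → ≈3.2 °C dip |
| `h_floor` | 0.35 | – | one full-pressure train from baseline reaches it |
| `tau_recovery` | 32 | min | ≈50 min bout before T_core re-crosses 34 °C |
| `vo2_basal`, `vo2_gain` | 1.29, 3.0 | ml·min⁻¹ | a full train drops VO₂ ≈ 37–39% |
| `rq_normal`, `rq_torpid` | 0.85, 0.72 | – | mixed-substrate vs fat oxidation |
| `rq_tau`, `rq_drive_floor` | 25 min, 0.9 | | see below |
| `noise_sd` | 0.05 | °C | telemetry sensor noise |

The RQ does not track the drive instantaneously. Substrate switching toward
fat oxidation is far slower than the fall in oxygen consumption, so the model
gives RQ first-order relaxation (`rq_tau`) toward a target that saturates at
the torpid level whenever the drive sits below `rq_drive_floor` of baseline.
With the defaults the RQ minimum (~0.73) trails the VO₂ minimum by roughly
half an hour, landing near the 45–55 min post-stimulus analysis window —
which is why that endpoint's search window sits so much later than the
temperature windows. Substrate use returns to mixed only once the
thermogenic drive has essentially normalized (`rq_drive_floor = 0.9`).

These defaults were fixed once, from the single-bout phenomenology (dip
depth ≈ 3.2 °C, VO₂ suppression ≈ 38%, bout ≈ 50 min, RQ minimum ≈ 0.73, a
24-h feedback session holding ≈ 33 °C), and are not adjusted per analysis.

**Integration.** Explicit Euler at `dt_min = 0.05` (simulation) or 0.1
(closed loop), both well under the fastest time constant (1/k_loss ≈ 29 min).
The unit tests bound the Euler error against an independent stiff integrator
(`deSolve::lsoda` at tolerance 1e-10): the trajectories agree to < 0.02 °C
and the bout minimum to < 0.005 °C. The discrete fixed point coincides
exactly with the analytic equilibrium $T_\mathrm{amb} + k_\mathrm{therm} H_0 /
k_\mathrm{loss}$, so equilibrium checks hold to machine precision.

## Thermal scene rendering and BAT tracking

`render_thermal_video()` paints, per frame: background at ambient, an
elliptical body, a thin tail strip, a warm head spot at the anterior tip, and
a circular BAT hotspot painted last with the same pixel-center-within-radius
rule that `roi_mean()` uses — so with zero noise the mean over the true
hotspot equals the programmed trace bit-exactly, which anchors the pipeline
tests. The hotspot default radius (5 mm) is deliberately larger than the
3-mm analysis ROI: a physical BAT depot is larger than the sampling ROI, and
the margin means millimeter-scale tracking errors stay inside the uniform
patch.

The tracking chain mirrors the automated procedure used with thermal cameras:

1. `segment_body()`: threshold at ambient + 4 °C (ambient estimated as the
   mode of the frame border, binned to 0.1 °C) and keep the largest
   connected component (`EBImage::bwlabel`).
2. `estimate_pose()`: centroid and principal axis from the coordinate second
   moments. Before the moments are taken the mask is cleaned by a 3×3
   morphological opening, which removes the tail (thinner than the kernel)
   so it cannot drag the centroid posterior or inflate the body length.
   Masks under 10 px are rejected as degenerate rather than guessed at.
3. Anterior disambiguation: the principal axis has two orientations. With an
   explicit `head_hint` coordinate the axis points toward it; the default
   `"warmer"` heuristic orients toward the body half with the hotter
   *upper-decile* temperature. Comparing upper deciles rather than half
   means matters: the head spot is small, and during a bout the (anterior)
   BAT hotspot cools below the body surface, which would flip a plain
   mean-based comparison.
4. `locate_bat_roi()`: disk center = centroid + 0.25 × body length along the
   anterior unit; radius 3 mm; centers outside the frame are flagged and
   the mean is taken over the in-frame intersection.
5. `roi_mean()`: a pixel belongs to the ROI iff its center lies within the
   radius (inclusive). No area weighting — the rule is deliberately simple
   enough to check against a brute-force loop, which the tests do on random
   frames.

`lowpass()` removes camera fluctuation with a zero-phase 4th-order
Butterworth filter; the cutoff (default 0.1 Hz) is configuration, since no
standard value exists for this step, and must sit below the Nyquist
frequency of the frame rate in use.

**Zero-phase filtering.** `signal::filtfilt` leaves large edge transients
(a constant-5 trace comes back off by up to 2 units at the edges), so the
package applies its own forward–backward pass: odd-reflection padding of
3×(filter order) samples and steady-state initial conditions per pass, the
textbook construction. A constant trace passes through unchanged to 1e-9,
and `lowpass()` additionally restores the finite-record mean exactly (exact
unit DC gain), so baseline means are unaffected by filtering.

## Windowed endpoints

All windows are half-open `[start, end)` seconds relative to the stimulus
onset; "the 7–12 min interval" maps to `[420, 720)`. The conventions are
bundled in `endpoint_config()`: T_BAT dips are searched 7–12 min post onset
against a 15-min baseline; T_core and VO₂ 0–30 min against the 5-min window
ending 1 min before onset; RQ 45–55 min against the 28-min window ending
2 min before onset. Extrema are taken sample-wise with no interpolation;
only RQ alignment interpolates (nearest VO₂ sample within 30 s). Bout onset
uses baseline mean − 2 sample SDs (n − 1 denominator; the convention is
configurable but sample SD is used everywhere in the package); the bout ends
at the first return of T_core to 34 °C after it first fell below. On noisy
telemetry a threshold-crossing time is inherently fragile — a single upward
noise excursion at the boundary ends the bout — so crossing-based endpoints
should be computed on filtered or noise-free traces; window-extremum
endpoints (max Δ) are robust as-is.

## Closed-loop controller

Pure bang-bang: fire iff the sampled T_core strictly exceeds T_set (34 °C);
at or below the setpoint the ultrasound stays off; a non-finite sample holds,
as the fail-safe direction. The inter-stimulus interval is interpreted as the
off-gap between consecutive stimuli, so the default train (10 s stimuli,
20 s ISI, 6 stimuli) has a 30 s onset-to-onset period and spans 160 s.
While a train is in progress new triggers are held (nothing is queued);
telemetry keeps sampling every minute regardless. After 12 h the pressure is
multiplied by 1.1 and the stimulus count becomes 8, for subsequent trains
only. Acoustic metadata (duty, PRF) is carried through but affects the plant
only via the pressure-scaled drive suppression.

Bang-bang control around this plant yields a limit cycle: T falls ≈1.5 °C
below the setpoint after each train and recovers in ≈45 min. The acceptance
property (≥90% of post-convergence samples in [T_set − 2, T_set + 0.5] over
100 seeded 24-h sessions, zero firings at or below T_set) holds with margin;
the drive floor is what keeps repeated trains from driving the cycle deeper
than a single train would.

## Photometry

Processing chain: zero-phase 2nd-order Butterworth high-pass (default
0.01 Hz) removes the photobleaching decay; z-scoring uses the full recording
with sample SD (a constant trace returns zeros with a warning); peaks are
local maxima filtered by topographic prominence (default 2 z units — no
published threshold exists, so it is exposed) and optionally a minimum
height. The height floor exists because prominence alone misbehaves on
band-passed noise: small bumps between two real transients are measured
against the deep valleys flanking them and can exceed 2 z.

Peak *apexes* of sharp-rise/slow-decay calcium transients are poorly
localized under noise (the decay is nearly flat over several samples), so
`peak_onsets()` walks back from each apex to the half-amplitude crossing of
the rise; programmed-versus-detected comparisons use these onsets. Window
statistics (largest peak amplitude, mean z, peaks per minute) are computed
over the 5 s before onset, 10 s of stimulation, and 15 s after offset, and
averaged across the stimuli of a train by `train_window_stats()`. "Peak
amplitude" means the maximum z value among detected peaks in the window (not
the maximum prominence), and a window without peaks reports amplitude 0 and
frequency 0. Evoked-activity onset is the first sample strictly above
pre-stimulus mean + 3 SD; the same rule serves ΔF/F traces in vitro, where
F₀ is the mean over a caller-chosen window and must be positive.

## Histology quantification

A cell is positive when its mean intensity strictly exceeds background
mean + 3 sample SDs; the boundary case is negative by construction.
Background statistics come from brain-mask-minus-cell-mask pixels; what
counts as "brain" (ventricles, section edges) is the caller's masking
decision. Published coexpression percentages are ambiguous about their
denominator, so `coexpression_fraction()` defaults to "B-positives among
A-positives" with the denominator exposed as an argument. Cell segmentation
itself is out of scope: the module consumes per-cell intensity tables, which
the synthetic generator produces with programmed positive fractions and
well-separated intensity distributions (positives N(60, 8), negatives
N(10, 1.5), background 10 ± 2, all a.u. and truncated at zero).

## snRNA-seq rules

The removals are strict inequalities taken verbatim from their statement:
mitochondrial fraction > 5%, feature counts > 7,500 or < 200 — so boundary
cells are kept, which the acceptance suite asserts exactly. LogNormalize is
natural-log `log1p(count / total × 10⁴)`, preserving the zero pattern.
Variable features rank by dispersion (variance/mean of normalized values;
zero-mean genes rank last) after removing the 139-gene IEG exclusion list;
the packaged list (`ieg_default.tsv`) is a curated default of mouse
immediate-early-gene symbols standing in for published IEG catalogues and is
caller-replaceable. Torpor-associated clusters come from k-means (k = 2 by
default — torpor vs not; the published cluster count is an outcome, not a
parameter, so k is exposed) on per-cluster mean expression of *Adcyap1*,
*Qrfp*, *Esr1*, seeded with multiple restarts; the higher-mean centroid is
the torpor set, and identical profiles degrade to a single group with a
warning. The activated cluster is the torpor cluster with the highest mean
of per-gene z-scored IEG expression; exact ties are flagged and broken by
cluster name. Graph-based community detection is deliberately *not*
reimplemented — cluster labels are an input (ground-truth labels in tests),
because the bespoke content is the filter/marker/IEG rules, not Louvain.

## What the generators do and do not emulate

The generators provide controlled truth: programmed dips, transient times,
positive fractions, planted cluster structure. They emulate the *structure*
of the real data (bleaching, stimulus-locked transients, Poisson counts with
lognormal depth and Beta-distributed mitochondrial contamination, a body
with tail and BAT hotspot in a cooler background) but not its full
messiness: no fur occlusion or camera radiometric drift, no isosbestic
channel or motion artifacts in photometry, no segmentation errors in cell
tables, no ambient-temperature drift, and Poisson rather than
overdispersed counts. A passing recovery test therefore demonstrates that
the algorithms are implemented correctly and are robust at realistic
noise levels — not that they would be robust to every artifact of a live
recording.

## Problem sizes and reproducibility

The test and acceptance workloads are sized for a single CPU: 113-frame
60×80 px videos at one frame per 15 s (100 videos for dip recovery),
100 photometry traces of 801 samples, 100 24-h closed-loop sessions at a
0.1-min step, and 100 count matrices of 2,000 genes × 3,000 cells for the
annotation chain. Every stochastic function takes an explicit seed and is a
pure function of (parameters, seed); `run_stage()` writes a manifest with
MD5 checksums of all inputs and outputs, and `rerun_from_manifest()`
reproduces any stage bit-identically. Thermal stacks are stored as 32-bit
float TIFF normalized to [0, 1] (the writer clamps outside that range) with
offset/scale in the sidecar CSV — exact to float32 resolution, about 1e-5 °C
over a 40 °C span.

## Known limitations

* The plant is a two-state caricature: no circadian rhythm, activity
  thermogenesis, or ambient-temperature dependence of the bout beyond the
  equilibrium shift; rewarming kinetics are free parameters chosen to give
  ~50-min bouts.
* Heart-rate endpoints are not modeled; ECG analysis is out of scope.
* Crossing-based bout endpoints (`uih_onset`, `uih_end`) assume the trace
  has been denoised; they deliberately implement the stated rule rather
  than a hysteresis variant.
* The warmer-end heuristic assumes the head end carries the hottest surface
  pixels; animals in unusual postures need an explicit `head_hint`.
* Multi-animal scenes, fur occlusion and radiometric calibration are out of
  scope for the tracker.
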