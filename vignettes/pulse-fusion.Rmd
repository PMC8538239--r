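---
title: "Camera-based heart rate by fusing color and motion pulse signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based heart rate by fusing color and motion pulse signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A camera pointed at a face records two independent traces of the cardiac
cycle. Each heartbeat changes the blood volume in the skin, which modulates
the color of facial skin regions by a fraction of an 8-bit count (remote
photoplethysmography, RPPG). Each ejection of blood into the aorta also
recoils the head by roughly half a millimetre — about a third of a pixel at
typical webcam face scale — which shows up in the vertical trajectories of
tracked facial points (remote ballistocardiography, RBCG). Both signals are
weak and each is vulnerable to a different enemy: RPPG to illumination
changes, RBCG to voluntary head and facial movement. Because the two failure
modes are nearly disjoint, fusing the signals is more robust than either
alone. `pulsefuse` implements this fusion pipeline end to end, together with
a synthetic generator that provides ground-truth heart rate, so every stage
is testable without recorded human data.

# Pipeline overview

```
frames ──► face box ──► ROIs ──► mean RGB traces ──► PBV projection ─┐
               │                                      band-pass, ICA │
               └──► 80-point grid ──► LK tracking ──► y-trajectories │
                                       band-pass, 2σ clip, pruning,  │
                                       PCA ──────────────────────────┤
                                                                     ▼
                                        standardize, sign-align, fuse
                                        (EA | PCA | ICA), windowed HR
```

## Geometry

From a face box the package derives four regions: forehead (middle 50% of
width, top 20% of height), nose (middle 50% of width, central 25% of
height), and two cheeks (20–35% and 65–80% of width, 45–70% of height).
The forehead is divided into 8×4 cells and the nose into 8×6, one tracked
point per cell center — 80 points in total. Points are carried between
frames by a 3-level pyramidal Lucas–Kanade tracker; the ROIs follow via a
least-squares similarity transform of the tracked points. If any point
moves more than 10 px between consecutive frames, the face is re-detected
and ROIs and grid are re-derived (`run_pipeline` reports these resets).

## Color path (RPPG)

Per frame, each of nose/left-cheek/right-cheek yields a spatial mean RGB
triple. Channels are mean-centered (removing the static skin tone) and
combined with the weight vector `w` solving `Q w ∝ pbv`, where `Q` is the
3×3 channel covariance and `pbv` is the normalized pulse blood-volume
direction `(0.33, 0.77, 0.53)` — the characteristic direction of
pulse-induced color change. This projection suppresses the dominant
distortions (common illumination) while keeping unit gain on the pulse.
The three per-region candidates are band-passed to 0.75–2.5 Hz (45–150
bpm), decomposed by ICA, and the component with the highest spectral SNR
becomes the RPPG signal.

## Motion path (RBCG)

The 80 y-trajectories are mean-centered, band-passed, and amplitude
corrected: samples beyond 2 standard deviations are replaced by the mean,
which blunts voluntary-movement transients. Channels whose spectral SNR
falls below the across-channel mean are pruned (facial expressions corrupt
the points over moving muscles, and artifact susceptibility is a fixed
property of a point's location, so pruning uses the whole recording).
PCA over the surviving channels yields up to five component series; the
highest-SNR one is the RBCG signal.

## Spectral SNR and heart rate

Throughout, component selection uses the in-band spectral signal-to-noise
ratio

```
SNR = max(PS) / (sum(PS) − max(PS))
```

where `PS` is the power spectrum restricted to 0.75–2.5 Hz. The heart-rate
readout is `60 ×` the frequency of the in-band spectral peak, with the FFT
zero-padded to at least 120 s worth of samples (≥ 0.44 bpm bins at 30 fps).

## Fusion

Both extracted signals are standardized to zero mean and unit variance
(pixel and color units are incomparable; without this one modality would
dominate), and the RBCG sign is aligned to RPPG by correlation — blind
source separation components carry an arbitrary sign, and ensemble
averaging two anti-phase copies of the pulse would cancel it. Three fusion
schemes are provided:

* **EA** — the ensemble average `(RPPG + RBCG)/2`;
* **PCA** — PCA of the signal pair, highest-SNR component;
* **ICA** — ICA of the signal pair, highest-SNR component.

## Windowed estimation

Heart rate is estimated per 30-s sliding window with 1-s stride, stamped
with the window's end time. Crucially, the whole extraction chain —
per-region ICA, PCA component selection, fusion — is re-run *inside each
window*, as an online system would. Spectral-SNR selection is only
informative while the heart rate is near-constant in the analyzed stretch;
run once over a recording with a drifting rate, the smeared pulse peak
loses to incidental narrowband noise and selection becomes arbitrary. The
whole-recording extractions are still returned in `$signals` for
inspection.

A window-end-stamped spectral estimate measures the *average* rate over its
window, so the matching reference at time `t` is the ground-truth mean over
`[t − 30, t]` (`windowed_reference()`), not the instantaneous truth at `t`.
Evaluating against the endpoint truth would charge the estimator a
built-in lag of up to half the window's rate change.

# The synthetic generator

`sim_config()` defines a recording; `scenario()` provides three presets
that differ only in illumination amplitude, movement rate, and expression
coverage:

| preset        | illum_amp | motion_rate /min | expression_fraction |
|---------------|-----------|------------------|---------------------|
| `normal`      | 0.2       | 0                | 0                   |
| `expressions` | 0.2       | 2                | 0.4                 |
| `hci`         | 1.5       | 6                | 0.4                 |

All other generator parameters are shared study-condition defaults:

| parameter       | default | unit       | what it models                                  |
|-----------------|---------|------------|-------------------------------------------------|
| `pulse_amp_rgb` | 0.2     | 8-bit      | blood-volume color modulation along `pbv`        |
| `bcg_amp`       | 0.35    | px         | cardiac head recoil (≈0.5 mm at ~0.7 px/mm)      |
| `jitter_px`     | 0.4     | px         | per-point tracking noise                         |
| `sensor_noise`  | 0.5     | 8-bit      | camera sensor / compression noise on ROI means   |
| `resp_amp`      | 1.5     | px         | respiratory head sway (irregular, harmonic-rich) |
| `sway_px`       | 0.3     | px         | postural micro-sway, broadband 0.3–3 Hz          |
| `color_noise`   | 0.25    | 8-bit      | wandering in-band color residue (AWB hunting)    |
| `amp_mod`       | 0.4     | —          | slow pulse-amplitude modulation depth            |
| `motion_amp`    | 14      | px         | transient voluntary head movements               |

Three of these deserve comment, because they are what makes the simulation
*hard* in the way real recordings are hard:

* **Respiration** is not a sinusoid: `noise_breathing()` integrates a
  wandering breath rate (0.2–0.35 Hz) through an asymmetric waveform with
  2nd–5th harmonics. The upper harmonics land inside the cardiac band and
  are the classic RBCG confounder; the rate *must* wander (drift well above
  the heart rate's own wander), because a perfectly regular breath would
  present a coherent in-band tone that captures SNR-based selection — real
  breathing is far less regular than a resting heart rate.
* **Color residue** is applied independently per channel and region — a
  perfectly common-mode distortion would be exactly nulled by the PBV
  projection, which no real light source or white-balance loop achieves.
* **Illumination** mixes a flicker band, a slow in-band wandering tone, and
  a broadband floor, with per-channel gains (1, 0.85, 0.7) for the same
  reason.

Amplitudes were calibrated once, before the test suite existed, so that the
single-modality error regime matches published camera-pulse studies
(seed-averaged MAE of roughly 1–2.5 bpm per single modality under the
`normal` preset, several bpm under `hci`, with RPPG biased high under
strong illumination and RBCG biased low by respiratory harmonics), and then
frozen. The test suite never tunes them.

Unless overridden, scenarios use a seeded physiological heart-rate
trajectory (`hrv_trajectory()`, a bounded random walk of a few bpm around
72) rather than a constant — a perfectly steady sitter has a perfectly
steady spectrum that no realistic recording shows. `render_clip()`
additionally rasterizes a recording into actual frames (textured moving
face patch) so the full video path — tracking, ROI maintenance,
re-detection — can be exercised and compared against the trace-level path.

# Worked example

```{r, eval = FALSE}
library(pulsefuse)

cfg <- scenario("normal", duration = 60, seed = 1)
rgb <- simulate_rgb(cfg)
trj <- simulate_trajectories(cfg)

res <- run_pipeline(list(traces = rgb$traces, traj = trj$traj),
                    method = c("EA", "PCA", "ICA"))
print(res)
summary(res)
plot(res)

est <- res$hr[res$hr$method == "EA", ]
ref <- windowed_reference(rgb$truth, est$time, res$window_s)
a <- agreement(est, ref)
print(a)
plot(a)   # Bland-Altman
```

# Numerical choices

* Band-pass: order-2 Butterworth, applied forward and backward
  (zero-phase), 0.75–2.5 Hz.
* ICA: deterministic symmetric FastICA (logcosh contrast, eigen-whitening,
  seeded orthonormal start); same seed, bit-identical result. The caller's
  RNG state is untouched. Non-convergence falls back to PCA with a warning.
* SNR near-ties (< 1e-9) resolve toward the lower dominant frequency.
* Pearson correlation of a constant series is reported as `NA`
  (undefined), never fabricated as 0 or 1.
* SDAE is the standard deviation of the *absolute* errors.

# Limitations

* SNR-based component selection assumes the pulse is the most coherent
  in-band process. When a corrupted modality presents a *narrowband*
  artifact — in the simulator this happens under the `expressions` preset,
  where band-limited expression noise shows window-local peaks sharper than
  the pulse's (whose power is split between the fundamental and its second
  harmonic) — selection can confidently pick the artifact. ICA fusion
  suffers most, precisely because it separates well: the isolated artifact
  component then competes directly with the isolated pulse on SNR. Ensemble
  averaging degrades more gracefully, and in our measurements EA and PCA
  retain the fusion benefit in every preset while ICA can fall slightly
  behind the better single modality under `expressions`. A selection rule
  with memory (tracking continuity across windows) would help but is beyond
  the implemented method.
* The 2σ amplitude correction suppresses transients but not sustained
  periodic artifacts.
* The tracker assumes a rigid, textured face patch; non-rigid deformation
  is modelled only through the expression noise, not rendered.
* Reference alignment uses nearest-neighbour matching within 0.5 s;
  estimates without a reference within tolerance are dropped and counted.
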