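---
title: "Phase-resolved functional lung MRI: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-resolved functional lung MRI: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(preful)
```

## Overview

`preful` turns a free-breathing 2D+t proton-MRI series of the lung into
regional ventilation, normalized perfusion and flow-volume-loop (FVL)
correlation maps, together with defect percentages (VDP, QDP) and
ventilation/perfusion match categories. The premise is frequency
separation: the acquired signal is a superposition of a slow
proton-density component driven by respiration (~0.2–0.3 Hz) and a faster
blood-inflow component driven by the cardiac cycle (~1–1.4 Hz), both well
below the Nyquist frequency of the acquisition (250 frames at 0.3 s,
Nyquist 1.67 Hz). Phase-sorting the frames by each physiological phase
reconstructs one average respiratory and one average cardiac cycle per
voxel without gating or contrast agents.

## Signal model and phantom

The dynamic phantom realizes the model the pipeline assumes:

* lung parenchyma: `S(x, t) = S0(x) (1 - a(x) r(t))` — inspiration dilutes
  proton density, so signal falls as the respiratory waveform
  `r(t) in [0, 1]` rises;
* blood-supplied voxels: `S(x, t) = S0(x) + A_q(x) c(t)` with the cardiac
  waveform `c(t)`;
* optional vertical diaphragm displacement (apex-weighted ramp), additive
  Gaussian or Rician noise, and defect regions that scale `a(x)` or
  `A_q(x)` down.

For uniform amplitude `a`, the regional-ventilation truth is analytic.
With `S_exp = S0`, `S_insp = S0 (1 - a)` and the mid position at
`r = 1/2`:

`RV = 100 (S_mid/S_insp - S_mid/S_exp) = 100 (1 - a/2) a / (1 - a)`

which is 10.556% for the default `a = 0.10`. All phantom parameters are
recorded in `phantom_spec()` with seeded, reproducible noise, and the
generator returns truth masks and the per-frame displacement field.

```{r phantom}
spec <- phantom_spec(grid_shape = c(64L, 64L), n_frames = 120L, seed = 1)
ph <- generate_phantom(spec)
ph$series
range(ph$truth$true_ventilation_map, na.rm = TRUE)
```

## Pipeline stages

1. **Coarse mask and respiratory signal.** A body/lung intensity mask on
   the temporal mean breaks the segmentation–registration circularity.
   The mask-mean signal is low-pass filtered (zero-lag, order-4
   Butterworth applied forward–backward with reflected end-padding;
   default cutoff 0.5 Hz). End-expiration peaks are signal maxima;
   respiratory phase is linear in time between consecutive peaks, and
   frames outside the first–last peak span are excluded.
2. **Reference frame and registration.** The registration target is the
   mid-expiration frame: the frame on a descending (post-peak) limb whose
   smoothed signal is closest to the midpoint of the median peak and
   trough levels (earliest frame on ties). All frames are registered to
   it by multi-resolution Horn–Schunck optical flow. Motion is estimated
   on temporally low-passed (< 0.6 Hz) frames so that cardiac inflow does
   not masquerade as motion, and the resulting flow warps the original
   frames. The Jacobi inner loop runs in compiled code with a convergence
   tolerance of 1e-3 px, and each frame's flow is warm-started from its
   already-solved temporal neighbour.
3. **Segmentation.** Classical baseline on the registered temporal mean:
   Otsu body mask, hole filling, a second Otsu threshold inside the body,
   morphological opening, two largest 4-connected components. A
   user-supplied mask bypasses the baseline.
4. **Cardiac phase and perfusion.** The seed signal (bright corridor
   voxels between the lungs) is band-passed to the cardiac band (default
   0.6–2.0 Hz, clipped below Nyquist); phase comes from the
   analytic-signal angle. Before cardiac phase-sorting, every voxel's
   time course is band-passed with a zero-phase FFT Butterworth filter:
   the respiratory modulation in lung is an order of magnitude larger
   than the inflow signal and would otherwise leak into the 15-bin
   cardiac cycle. Voxel amplitude is the peak-to-trough range of the
   reconstructed cycle; the full-blood reference region is the
   highest-amplitude connected region in the inter-lung corridor above an
   adaptive floor (P75 of corridor amplitudes, guarded by 30% of the
   corridor maximum), and `Q = 100 * amplitude / mean(blood amplitude)`,
   so the blood-region mean is 100% by construction.
5. **Respiratory cycle and ventilation.** Frames are sorted into 15
   respiratory-phase bins (`floor(phase * n_bins)`, per-voxel bin means;
   empty bins within a 30% budget are filled by circular inverse-distance
   interpolation and flagged). With `S_insp` the cycle minimum, `S_exp`
   the maximum and `S_mid` the value at the reference frame's bin,
   `RV = 100 (S_mid/S_insp - S_mid/S_exp)`. Zero-modulation voxels map
   to 0%; non-positive `S_insp` is no-data.
6. **FVL correlation.** Per voxel, the normalized respiratory cycle is a
   volume proxy; its circular central difference is the flow curve; the
   map is the Pearson correlation with the mean flow curve of the healthy
   reference region (largest 4-connected component within the [P80, P90]
   ventilation band).
7. **Defects and metrics.** Strict thresholds: ventilation defect below
   `0.40 * P90(RV)` (or FVL correlation below 0.9 in FVL mode), perfusion
   defect below 2%. Values exactly at a threshold are non-defect. The
   four categories partition the valid lung; VDP/QDP compose from them
   exactly, and the non-defect share is the closure remainder so the four
   percentages sum to exactly 100. The thresholds were calibrated at
   1.5 T with a FLASH sequence; at other field strengths they are a
   transferred convention, which every report records.

```{r pipeline}
res <- suppressMessages(run_preful(ph$series, run_config(
  registration = list(alpha = 2, n_iter = 60L, n_levels = 2L,
                      n_warp = 2L))))
unlist(res$report[c("mean_ventilation", "mean_perfusion", "vdp", "qdp",
                    "vqm_defect", "vqm_nondefect")])
```

## Cohort statistics

Two-group comparisons pass both samples through a Shapiro–Wilk gate at
alpha 0.05: a pooled-variance t test when both pass, otherwise a
two-sided Mann–Whitney U test (exact for small tie-free samples).
Zero-variance samples bypass the gate to the nonparametric branch with a
warning. More than two groups use classical one-way ANOVA; correlations
are pairwise-complete Spearman; dispersion is reported as SEM. Severity
strata on vital capacity in percent predicted close the printed integer
bins continuously: mild >= 88, moderate 58–87.99…, severe < 58.

## Numerical conventions

* Percentiles: linear interpolation between closest ranks
  (`quantile(type = 7)`) everywhere.
* Connected components: 4-connectivity, breadth-first labeling in
  deterministic raster order.
* All filters zero-lag; phase bins use the floor convention with edge
  phases assigned to their own bin.
* `n_bins = 15` for both cycles balances bin occupancy (250 frames)
  against phase resolution.
* Everything is deterministic given input, configuration and seed;
  repeated runs produce bit-identical reports.

## Problem sizes and runtime

The default protocol (128 x 128, 250 frames) runs in roughly 15 s on one
CPU; unit tests use 64 x 64 x 120 phantoms with a lighter registration
setting. The acceptance script exercises the full-size protocol.

## Limitations

* The phantom is a 2D geometric idealization (elliptical lungs, disc
  vessel, separable waveforms); it validates numerics and contracts, not
  physiological realism.
* Defect thresholds are a 1.5 T calibration transferred verbatim; on
  other hardware they define conventions, not clinical cut-offs.
* The FVL correlation is amplitude-blind by construction (per-voxel
  normalization), so on noiseless data an amplitude-only defect leaves
  the FVL map at 1; FVL-mode VDP is therefore only informative when
  waveform shape or timing differs.
* Respiratory phase is assigned by time interpolation within each breath
  rather than amplitude binning — a documented divergence risk against
  vendor implementations.
* Single slice only; no through-plane motion model.
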