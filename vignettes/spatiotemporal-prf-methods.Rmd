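---
title: "Spatiotemporal pRF modeling: model, estimation and validation choices"
author: "stprf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal pRF modeling: model, estimation and validation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stprf)
```

## The model

`stprf` models the BOLD time-series of a voxel in a visual structure (it was
designed with the human lateral geniculate nucleus in mind) as the
composition of four stages:

1. **Spatial pooling.** A two-dimensional isotropic Gaussian receptive field
   `G(x, y) = exp(-((x0-x)^2 + (y0-y)^2) / (2 sigma^2))` is integrated
   against the binary stimulus aperture `S(x, y, t)` frame by frame (inner
   product over grid cells scaled by the cell area). `x0, y0` are the pRF
   center in degrees of visual angle, `sigma` its dispersion.
2. **Temporal channels.** The fine-time luminance flicker of the stimulus is
   passed through two temporal receptive fields spanning one volume
   acquisition: a *sustained* channel, a Gaussian in time with exponent
   `-(t - t0)^2 / (2 pi tau)` normalized to unit area, and a *transient*
   channel, its first derivative. Channel outputs are half-wave rectified
   and averaged within each volume, giving per-volume gains `gS[i], gT[i]`.
   These mimic the parvocellular (sustained, low-pass in flicker frequency)
   and magnocellular (transient, band-pass) response modes; a voxel mixes
   them with a weight `omega` (1 = purely sustained, 0 = purely transient).
3. **Hemodynamics.** The neural drive `s[i] * (omega gS[i] + (1-omega) gT[i])`
   is convolved causally with a double-gamma HRF whose time-to-peak is
   shifted by a delay `delta`.
4. **Scaling.** The result is scaled by an amplitude `beta` (absorbing the
   unit-free BOLD gain, dominated in the LGN by the vascular hilum) and
   shifted by a baseline `mu`.

Six parameters `(x0, y0, sigma, omega, beta, mu)` are voxelwise; the HRF
delay `delta` and the temporal dispersion `tau` are *yoked*: shared by all
voxels of a session and estimated in tandem with the voxel fits. Neither
`tau` nor the channel amplitude normalization is given a physiological
reading; they fix the scale against which `omega` is interpreted.

## Numerical and design choices

**Flicker phase and per-volume gains.** Flicker phase resets at each volume
onset, and channel kernels are applied zero-phase (centered on their `t0`)
volume by volume. Consequences: per-volume gains are stationary functions of
the volume's flicker frequency alone, so they are computed once per unique
frequency — the central speed lever of the fitter — and the gain of a
frequency with a whole number of cycles per volume equals the kernel's
attenuation divided by pi. Frequencies with fractional cycles per volume
pick up a small rectification ripple (the last half-cycle is unpaired);
monotonicity statements about the sustained channel therefore hold exactly
on the even-frequency grid (whole cycles at TR = 1.5 s) used in the tests.

**Channel gain balance.** A raw derivative kernel responds to a sinusoid at
frequency `f` with exactly `2 pi f` times the amplitude of the unit-area
sustained kernel (about 60–125x at 10–20 Hz). At that scale every mixture is
effectively transient-dominated and `omega` carries almost no information at
realistic noise levels: in a simulation at SNR 2 the median `omega` error
was 0.33 while the spatial parameters were recovered to ~0.15 deg. The
transient kernel is therefore scaled by `1 / (2 pi * 15 Hz)` so that both
channels have equal rectified gain at 15 Hz, the midpoint of the bar
stimulus's two flicker frequencies. This is a monotone reparameterization of
`omega` — shape, zero-sum, antisymmetry, extrema and every qualitative
frequency-tuning property are untouched — and after it the same simulation
recovers `omega` with median error 0.03.

**Default `tau = 2e-5`** (effective kernel SD `sqrt(pi tau)` ~ 7.9 ms)
places the transient channel's band-pass peak near 20 Hz inside the 2–60 Hz
experimental band, so the sustained gain is larger at 10 Hz, the transient
gain larger at 20 Hz.

**HRF constants.** Two gamma densities with scale 1 s, response mode at
`5 + delta` s and undershoot mode at `15 + delta` s, undershoot ratio 1/6,
peak-normalized. `delta` is bounded to ±3 s.

**Stimulus geometry.** The display subtends 26 x 20 deg, but the default
*modeling field* for the bar stimulus is the central 20 deg square
(`fieldGeometry()`, 81 x 81 grid at 0.25 deg), matching the ±10 deg spatial
search bounds. With a 5 deg bar sweeping edge-to-edge over that square,
interior pixels are stimulated for 25% of the run (duty cycle 0.25; the
global pixel-volume on-fraction is 0.23 because the bar partially exits at
the sweep ends). No bar geometry over the full 26 x 20 display reaches a
0.25 duty cycle, which is why the square field was adopted. Grids must have
equal x/y spacing; odd point counts keep fixation on the grid.

## Estimation

**Two-phase voxel fit.** Phase 1 evaluates an 11 x 11 x 8 x 5 lattice over
`(x0, y0, sigma[log-spaced 0.25–8 deg], omega)` against the stimulus
downsampled to 5% resolution (floored at 11 grid points per axis — below
that the bar's position is lost), solving `beta, mu` per lattice point by
OLS; the bounds then shrink to the incumbent's one-cell neighborhood for a
second pass. Ties break toward the smallest `sigma`, then the smallest
`|x0| + |y0|`. Phase 2 refines by Nelder–Mead over `(x0, y0, sigma, omega)`
with `beta, mu` profiled by OLS at every proposal, which is the exact RSS
profile over all six parameters; a six-dimensional simplex instead crawls
along the shallow `omega`–`beta` valley and stalls at visibly wrong mixtures
despite r² > 0.9999. Out-of-bounds proposals are rejected with an infinite
penalty; spatial bounds are ±10 deg, `omega` in [0, 1].

**Yoked globals.** `fitYoked()` alternates (a) voxelwise fits with
`(delta, tau)` frozen and (b) a Nelder–Mead refinement of
`(delta, log tau)` minimizing the summed RSS over voxels with r² > 0.1, with
the voxels' *spatial* parameters frozen. Because the prediction is linear in
`(omega beta, (1-omega) beta, mu)` once the spatial parameters are fixed,
step (b) re-profiles those three per voxel in closed form inside the
objective. This has the same fixed point as holding all six fixed but
converges in 2–3 outer iterations, whereas strict block descent creeps
geometrically (each voxel's `omega` keeps absorbing the stale `tau`). The
loop stops when `delta` moves < 0.05 s and `tau` < 1% (defaults), max 10
outer iterations.

**Identifiability of `tau`.** With the bar experiment's two flicker
frequencies alone, `tau` is *exactly* unidentifiable: the two per-volume
gain sequences span the same two-dimensional signal subspace for every
`tau`, so each voxel's channel amplitudes absorb any `tau` with zero change
in RSS. (This is the sharp version of the `omega`–`tau` degeneracy the
yoking is designed around; yoking alone does not break it when only two
frequencies are shown, except weakly through the `omega` bounds.) Validation
phantoms that must recover `tau` are therefore driven by the bar sweep
concatenated with a full-field frequency-sweep run (`concatMovies()`), i.e.
by both experiments of the design; with ~30 distinct frequencies `tau` is
pinned to a fraction of a percent on noiseless data.

## The synthetic phantom

`makePhantom()` builds an ellipsoidal voxel lattice (~250 mm³ by default at
1.5 mm spacing, ~74 voxels) with smooth truth fields emulating the known
organization of the LGN: eccentricity growing from the posterior (foveal)
to the anterior pole, polar angle covering the contralateral hemifield
along the superior-medial to inferior-lateral axis, receptive-field size
`sigma = 0.5 + 0.4 * ecc`, a sustained-to-transient weight gradient planted
at a configurable coronal-plane angle (default 36 deg from horizontal,
dorsolateral to ventromedial), and a Gaussian amplitude bump at the
ventromedial "hilum" (the vascular entry point that dominates BOLD gain).
Noise is additive Gaussian with optional AR(1) correlation, configured
either as a fixed SD or as a per-voxel SNR (`sd(signal)/sd(noise)`); the
phantom never hard-codes a noise level. Motion traces are smooth random
drifts plus planted step displacements exceeding the 0.4 mm framewise
displacement threshold — one censored volume per spike.

What the phantom does *not* emulate: spatial noise correlations,
physiological (cardiac/respiratory) signals, scanner drift, susceptibility
distortion, partial-volume mixing between neighboring voxels, and the 2x
spatial resampling applied to real scans. Passing recovery tests on the
phantom therefore demonstrates correctness of the estimator under the
model's own assumptions, not robustness to everything real data contain.

**Cluster phantoms.** `makeClusterPhantom()` plants k response families in
full-field time-series, differing only in amplitude (`beta`, emulating the
hilum gain; default tiers 6/0.8/0.05 = strong, moderate, unstimulated) or
only in temporal weight (`omega`), with every other parameter drawn
independently of the family. Noise is expressed relative to the
unit-amplitude signal SD so a voxel's SNR is ~`beta`. The amplitude tiers
were calibrated once against the geometry of the correlation-profile
features: with tiers 4/1 the two driven families sat closer together
(feature distance ~1.4) than the unstimulated family's internal spread
(~sqrt(2)) and average linkage merged them on some seeds; at 6/1/0.05 the
three families are recovered exactly on every probe seed. This realizes
the "clustering is amplitude-dominated" behavior as a testable
planted-structure recovery.

## Validation problem sizes

The acceptance checks (test suite and `scripts/acceptance.R`) run at these
sizes, chosen to exercise each property at desk scale: channel sweeps over
30 even frequencies; coarse-grid/enumeration equality for 20 voxels on a
frozen 5^4 lattice; noiseless yoked recovery on a 55-voxel phantom against
the bar + full-field stimulus on a 0.5 deg grid; noisy recovery on 115
voxels at SNR 2; bootstrap reliability on a 15-voxel, 12-run phantom at
per-run SNR 0.3 (the low channel-SNR regime in which the weight's error
declines visibly more slowly than the spatial parameters') with sample
sizes {2, 4, 8} and 6 replicates; clustering and label-regression studies
on 75-voxel phantoms over 50 seeds; Rayleigh null calibration over 500
draws of 1000 uniform angles.

## Known limitations

* `tau` (and hence the absolute meaning of `omega`) is defined only up to
  the channel normalization; comparisons of `omega` across analyses are
  meaningful only under the same kernel conventions.
* With two-frequency stimuli, report `omega` conditional on a fixed `tau`;
  do not interpret a yoked `tau` estimated from such data.
* The coarse grid assumes the pRF center lies within ±10 deg and `sigma`
  within 0.25–8 deg; pRFs far outside the stimulated field degrade to the
  boundary.
* Voxels are fitted independently; no spatial regularization is applied.
* The multinomial label regression can be quasi-separated when clusters are
  perfectly explained by one parameter; it is reported with a warning, and
  the companion linear model (which the summary F and r² come from) is the
  stable quantity in that regime.
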