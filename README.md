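# stprf — spatiotemporal population receptive field modeling

`stprf` estimates **spatiotemporal population receptive fields (pRF)** from
BOLD fMRI time-series. It was built for small subcortical visual structures —
the human lateral geniculate nucleus (LGN) in particular — where the
magnocellular (transient) and parvocellular (sustained) subpopulations can
only be told apart *functionally*, and where the richly vascularized hilum
imposes a strong spatial gradient on BOLD amplitude that must be modeled
explicitly or it dominates every data-driven segmentation.

## The model

Each voxel's signal is modeled as

```
R(t) = mu + beta * [ HRF_delta  *  s(t) * ( omega * gS(t) + (1 - omega) * gT(t) ) ]
```

* `s(t)` — overlap of the stimulus aperture `S(x, y, t)` with an isotropic
  2D Gaussian receptive field `G(x, y)` centered at `(x0, y0)` with
  dispersion `sigma` (degrees of visual angle);
* `gS, gT` — per-volume gains of a **sustained** temporal channel (a
  unit-area Gaussian in time, dispersion `tau`) and a **transient** channel
  (its first derivative, gain-balanced at 15 Hz), each applied to the
  fine-time flicker waveform of the stimulus and half-wave rectified. The
  sustained channel is low-pass in flicker frequency, the transient channel
  band-pass, so flicker-frequency changes produce an amplitude modulation
  whose size reveals the mixture weight `omega` (1 = purely sustained /
  parvocellular-like, 0 = purely transient / magnocellular-like);
* `HRF_delta` — a double-gamma hemodynamic response with fitted delay
  `delta`; `beta` and `mu` are the voxel's amplitude and baseline.

`(x0, y0, sigma, omega, beta, mu)` are estimated per voxel by a two-phase
procedure (adaptive coarse grid search on a 5%-resolution stimulus, then
Nelder–Mead refinement with `beta, mu` profiled by least squares). The
hemodynamic delay `delta` and temporal dispersion `tau` are **yoked** —
shared across all voxels and estimated in alternation with the voxel fits
over the r² > 0.1 subset.

Around the estimator the package provides: bar-sweep and full-field flicker
stimulus construction, framewise-displacement volume censoring and run
averaging, model-free agglomerative clustering of voxel time-series with
multinomial label regression, circular statistics of the
sustained-to-transient weight gradient (mean direction, CI, Rayleigh test),
bootstrap reliability curves over scanning runs, and a synthetic LGN-like
phantom generator so the entire pipeline is testable without scanner data.

## Worked example

Simulate a small phantom, fit it, and read off the recovered organization:

```r
library(stprf)

geom  <- fieldGeometry(spacingDeg = 0.5)           # central 20 deg square
movie <- concatMovies(                             # both experiments:
  makeBarStimulus(geom),                           #   8-pass bar sweep
  fullfieldMovie(makeFullfieldSchedule(nTrials = 30, seed = 11), geom))

phantom <- makePhantom(phantomConfig(voxelSizeMm = 2.2,
                                     delta = 0.3, tau = 2.8e-5))
data <- simulateRuns(phantom, movie, noise = list(snr = 4), nRuns = 2,
                     seed = 1, motionSpikes = 1)

Y   <- meanRun(data)                               # censor + average runs
fit <- fitYoked(Y, movie, initGlobals = globalParams(0, 2e-5))
fit

gv <- weightGradient(voxelCoords(phantom), fitTable(fit)$omega)
coronalAngle(gv, "right")
```

Output:

```
PrfFitSet: 21 voxels (21 with r2 > 0.1), delta 0.2958 s, tau 2.843e-05, 2 outer iterations
[1] 35.86779
```

The fit recovers the session-wide hemodynamic delay (`delta`, planted at
0.3 s) and temporal dispersion (`tau`, planted at 2.8e-5) together with each
voxel's receptive field; the weight gradient's coronal angle recovers the
planted 36-degree dorsolateral-to-ventromedial axis.

A command-line interface wraps the same pipeline
(`inst/exec/stprf simulate|fit|bootstrap|cluster|gradient|report`), writing
TSV/NIfTI/JSON outputs plus a provenance record; identical configuration and
seed give byte-identical tables.

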