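# tubeflex

Quantitative characterisation of semiflexible filaments — designed protein
nanotubes, actin, and similar micron-scale polymers — from fluorescence
time-lapse data, electron-micrograph outlines, and thermal denaturation
curves.

## What it computes

**Persistence length from shape fluctuations.** A filament confined to two
dimensions and fluctuating thermally obeys the worm-like-chain relation
between its contour length *L* and the mean square of its end-to-end
distance *R*:

⟨R²⟩ = 4 Lp² [ 2 exp(−L / 2Lp) − 2 + L/Lp ]

where Lp is the persistence length. The package measures (L, ⟨R²⟩) per
filament — either from tracked image stacks or from externally produced
node traces — averaging R² over 100–200 frames, and estimates Lp by
nonlinear least squares of this relation across filaments. An independent
estimator based on the tangent autocorrelation decay exp(−s / 2Lp) is
provided as a cross-check.

**Filament tracking.** Image stacks are converted to 8-bit (one affine map
for the whole stack), each frame is smoothed, thresholded, morphologically
skeletonised, and each skeleton's longest endpoint-to-endpoint path becomes
an ordered node trace (1 px node spacing by default, with sub-pixel ridge
refinement and half-maximum endpoint localisation). Traces are linked
across frames by nearest-centroid matching. Snake-style text exports from
interactive tracers can be read directly and bypass this module.

**Tube-length morphometry.** Tube lengths are computed from closed traced
outlines as half the polygon perimeter, the longest *n* (default 150) per
condition are selected, and conditions are compared with a two-sided
Welch's t test (Welch–Satterthwaite degrees of freedom, raw p values).

**Thermal stability.** Denaturation curves (e.g. CD ellipticity at 222 nm
vs temperature) are fitted with a four-parameter logistic; the melting
midpoint Tm is the fitted inflection temperature.

**Synthetic data.** Every stage is testable without external data: the
package samples equilibrium 2D worm-like chains with known Lp (tangent
increments N(0, ds/Lp), giving the exact 2D autocorrelation), renders them
into multi-page TIFF movies with a Gaussian PSF, Poisson shot noise and
camera read noise, and simulates sigmoidal melt curves.

## Worked example

Simulate 55 filaments (contour lengths 2–15 µm) at a ground-truth
persistence length of 19.7 µm, observed over 150 independent frames each,
and recover Lp:

```r
library(tubeflex)

set.seed(1)
lengths <- runif(55, 2, 15)
cfg <- synthetic_config(lp_true = 19.7, contour_lengths = lengths,
                        n_filaments = 55, n_frames = 150,
                        ds = 0.05, rng_seed = 1)
stacks <- sample_ensemble(cfg)
tab <- mechanics_table(stacks)   # one (L, <R^2>) point per filament
head(tab, 3)
#>   filament_id    L      msR n_frames     sd_R2
#> 1        F001 5.45 28.53790      150 0.9892158
#> 2        F002 6.80 43.45661      150 2.2318841
#> 3        F003 9.40 81.45085      150 5.4636264

fit_persistence_length(tab)
#> 2D worm-like-chain fit of <R^2>(L)
#>   persistence length: 20.09 um (SE 0.172 um)
#>   points: 55   residual norm: 4.403 um^2

tangent_correlation_lp(stacks)   # independent cross-check
#> Tangent-correlation persistence length
#>   lp = 19.9 um (decay length 39.81 um)
#>   8250 traces, 146539350 node pairs
```

The fitted 20.09 ± 0.17 µm and the tangent-correlation 19.9 µm both recover
the 19.7 µm ground truth to within ~2%. The same `mechanics_table()` +
`fit_persistence_length()` path accepts tracked stacks from
`trace_filaments()`/`link_frames()` (pass `pixel_size` to convert pixel
traces to µm) or traces read with `read_trace_table()`/`read_snakes()`.

A melt-curve fit works the same way:

```r
cu <- simulate_melt_curve(tm = 46.2, k = 2, noise_sd = 0.36, seed = 1)
fit_sigmoid_tm(cu)
#> Four-parameter logistic melt fit
#>   Tm = 46.285 degC (SE 0.0661), slope k = 1.99 degC
#>   baselines: folded -19.92, unfolded -1.948
```

A thin command-line front-end over these functions (subcommands
`simulate`, `render`, `track`, `fit-lp`, `tubelen`, `compare`, `melt`)
is installed at `inst/cli/tubeflex.R`.

## Vignette

`vignettes/tubeflex-methods.Rmd` documents the model, the estimators and
their assumptions, all tunable parameters with units and defaults, what the
synthetic generator does and does not emulate, and known limitations
(notably the resolution-induced stiffening bias of image-based tracking).
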