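---
title: "Filament mechanics, morphometry and melt fitting with tubeflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filament mechanics, morphometry and melt fitting with tubeflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubeflex)
```

## The model

A semiflexible filament is described by the worm-like chain: a continuous
curve whose tangent angle diffuses along the arc length $s$ with a rate set
by the persistence length $L_p$. Confined to two dimensions (as filaments
are when held near a surface by an evanescent excitation field and a
depletion agent), the tangent autocorrelation is

$$\langle \cos(\theta(s + \Delta) - \theta(s)) \rangle = e^{-\Delta / 2L_p},$$

and integrating it twice over the contour gives the mean-square end-to-end
distance of a chain of contour length $L$:

$$\langle R^2 \rangle = 4 L_p^2 \left[ 2 e^{-L/2L_p} - 2 + L/L_p \right].$$

`wlc_mean_r2()` implements this closed form; the test suite verifies it
against direct numerical integration of the autocorrelation to $10^{-8}$
relative accuracy. The estimation pipeline measures one $(L, \langle R^2
\rangle)$ point per filament — $R^2$ averaged over many statistically
independent snapshots of the fluctuating shape — and fits $L_p$ across
filaments by nonlinear least squares (`fit_persistence_length()`).

Two assumptions matter. First, frames must be far enough apart in time that
shapes decorrelate; the per-filament average then converges as
$1/\sqrt{n_\mathrm{frames}}$, and 100–200 frames is the customary window
(`mean_square_r2()` warns outside it). Second, the estimator loses leverage
when every filament is much shorter than $L_p$: in that regime
$\langle R^2\rangle \approx L^2 (1 - L/6L_p)$, so a relative error
$\epsilon$ in measured $L$ propagates to roughly $12 L_p / L \cdot
\epsilon$ in $L_p$. With $L \le 15\,\mu m$ and $L_p \approx 20\,\mu m$ this
amplification is about one order of magnitude — the reason filaments
spanning up to $15\,\mu m$ (and ideally longer) are needed for a stable
estimate, and the reason `fit_persistence_length()` flags fits with
$\hat L_p > 10 \max(L)$ as beyond the data's support.

### Numerical details

* For $L/L_p < 10^{-2}$ the bracket in the closed form cancels
  catastrophically in double precision; a fourth-order series
  $L^2(1 - x/6 + x^2/48 - x^3/480)$, $x = L/L_p$, is used there. Both
  branches agree to ~$10^{-11}$ relative at the switch point.
* The fit starts from $\mathrm{median}(\langle R^2\rangle / 4L)$ — exact in
  the long-chain limit — and is bounded to $L_p > 0$. It is unweighted by
  default (each filament one vote); inverse-variance weighting by
  $\mathrm{sd}(R^2)^2 / n_\mathrm{frames}$ is available via
  `weighted = TRUE`.
* Points with $\langle R^2 \rangle > L^2$ are rejected outright (impossible
  geometry, always an upstream error), and all-equal $L$ values raise a
  rank-deficiency error.

### The cross-check estimator

`tangent_correlation_lp()` estimates $L_p$ without using endpoints at all:
it pools $\cos \Delta\theta$ over all node pairs of all traces, bins by arc
separation, and regresses $\log C$ on separation through the origin
(weights $n C^2$, since $\mathrm{var}(\log \hat C) \propto 1/(n C^2)$),
returning half the fitted decay length. Rigid traces produce no resolvable
decay and are reported with a `lower_bound` flag rather than a number taken
at face value. Agreement between the two estimators on the same data is a
strong internal consistency check; the test suite requires 15%.

## The synthetic generator

`sample_wlc_chain()` discretises the chain at arc step `ds`: tangent
increments are i.i.d. $N(0, ds/L_p)$, which makes
$\langle\cos\Delta\theta\rangle = e^{-ds/2L_p}$ *exactly*, so the sampled
ensemble has the exact 2D worm-like-chain autocorrelation at the node
scale, not merely asymptotically. The default `ds = min(0.05 µm, L/200)`
keeps the residual discretisation error of $\langle R^2\rangle$ (measured
against the closed form) in the $10^{-5}$ range, far below fitting noise.

`sample_ensemble()` draws each frame as an independent equilibrium shape.
Real movies are temporally correlated Brownian dynamics; independence is
deliberate — the estimator assumes only equilibrium statistics, and
independent draws maximise information per frame while avoiding relaxation-
time parameters the analysis never uses. Each filament keeps a fixed anchor
across frames so frame linking sees a quasi-static object. Ensembles are
bit-reproducible from `rng_seed`.

`render_frames()` draws each chain by accumulating an isotropic Gaussian
PSF along the polyline at quarter-pixel arc sampling (deposited intensity
proportional to length — verified to 3% in the tests), scales the noiseless
frame to `peak_intensity`, then adds background, Poisson shot noise and
Gaussian read noise and quantises to the camera bit depth. Defaults emulate
an EMCCD behind a 60× objective: 0.267 µm/px (16 µm camera pixels / 60×),
PSF σ = 1 px, 40 ms frame interval. Pixel size and PSF width are
conventions chosen here, not measured facts, and are fully configurable.

What the generator does **not** emulate: 3D bending projected to 2D,
excluded volume and self-crossing physics, filament elongation or turnover,
photobleaching, depletion-agent interactions, and temporal correlation.
Passing tests therefore demonstrate correctness of the estimators under the
model's own assumptions, not robustness to every property of real TIRFM
data.

## Tracking

`trace_filaments()` replaces interactive snake tracing with a deterministic
pipeline: Gaussian smoothing (σ = 1 px default), global thresholding (Otsu
default; a fixed fraction of the intensity range is available and preferable
for clean single-filament frames), Zhang–Suen skeletonisation, longest
endpoint-to-endpoint geodesic through each skeleton component (ties broken
by path intensity), smoothing-spline resampling at 1 px node spacing, then
two sub-pixel corrections:

* **ridge refinement** — each node moves to the intensity centroid along
  its local normal, since skeleton pixels are grid-quantised but the PSF
  ridge is not;
* **end relocation** — thinning retracts skeleton ends by roughly the
  stroke half-width, so each end is extended along its tangent to the
  half-maximum crossing of the smoothed profile. The reference ridge height
  is sampled a few pixels inside the trace because the tip itself sits in
  the end roll-off; for a Gaussian-profile filament the half-max crossing
  coincides with the true filament end.

On noiseless rendered data this tracks a 50 px straight filament and a
20 px-radius semicircle to sub-pixel contour and endpoint accuracy (the
acceptance tests require 2% / 1 px). Traces shorter than `min_length_px` or
touching a border margin (default 5 px; truncated filaments bias $L$ and
$R$ jointly) are dropped, and node order is canonicalised to the
lexicographically smaller endpoint, which makes output invariant to 180°
image rotation.

`link_frames()` performs greedy nearest-centroid linking with a maximum
displacement gate, deterministic tie-breaking towards the older stack, gap
counting, and flagging of stacks shorter than `min_frames` (default 100).
Crossing filaments are not disambiguated — a stated non-goal; crowded
fields fragment into short flagged stacks rather than failing.

### Known limitation: resolution-induced stiffening

A tracker cannot recover contour length stored in bending modes below the
optical resolution; smoothing therefore reports slightly short $L$ and a
slightly straightened shape. Because of the error amplification discussed
above, even a ~1% contour deficit inflates image-based $\hat L_p$ by tens
of percent in the stiff regime at 0.267 µm/px. The chain-validation test in
this package renders at 0.1 µm/px, where the deficit is small and the
image-based estimate tracks the ground-truth-trace estimate within 10%. At
TIRFM-like sampling, image-based estimates should be read as modestly
biased upward relative to trace-based ones; interactive snake tracers share
the same physics.

## Morphometry

`half_perimeter_length()` assumes the traced outline is a thin closed loop
hugging the tube, so perimeter ≈ 2 × length; the width contribution is not
corrected. Self-intersecting outlines warn but still return a value (the
operator decides). `select_longest()` reproduces the published longest-150
selection step verbatim — a deliberate selection bias that is part of the
procedure being reimplemented, not a recommendation. `welch_t_test()`
reports the raw two-sided Welch p value with Satterthwaite degrees of
freedom; no multiple-testing correction is applied because the procedure it
mirrors reports raw pairwise p values. Degenerate zero-variance input
follows a stated convention (p = 1 for constant equal samples, error
otherwise) since real length data never hits it.

## Melt fitting

`fit_sigmoid_tm()` fits a four-parameter logistic
$f(T) = b_f + (b_u - b_f)/(1 + e^{-(T - T_m)/k})$ by least squares, with
$T_m$ the inflection temperature — the conventional reading of a melting
midpoint. Constant baselines are the default: on a typical 50-point curve,
sloped baselines trade bias for variance and are only identifiable when
both plateaus are long (they are available via `sloped_baselines = TRUE`).
The fit is direction-agnostic (folded CD at 222 nm is negative; nothing
assumes a sign) and invariant to affine rescaling of the signal axis.
Initial guesses come from the data (outer-tercile means for the baselines,
the half-transition temperature for $T_m$) and a small ladder of slope
starts guards against the occasional singular-gradient start. Fits with no
resolvable transition (amplitude under ~3 residual SDs) or with $T_m$
outside the measured range return `converged = FALSE` with a diagnostic
instead of a misleading number.

At 2% amplitude noise and 1 °C sampling over 20–70 °C, the estimator's bias
is below 0.1 °C and single-curve recovery is well within 0.3 °C — both
checked in the test suite.

## Problem sizes used in the tests

The packaged checks run at desk scale, chosen to keep the full suite around
a minute while leaving comfortable statistical margins: ensemble-fidelity
checks use 3 000–5 000 chains per condition; persistence-length recovery
uses the full 55 × 150 (nanotube regime) and 37 × 150 (actin regime)
ensembles; the seeded-replicate recovery study uses 5 replicates of 25 × 100
per stiffness regime; Tm recovery uses 100–300 replicate curves; the
rendered-movie chain validation uses 6 filaments × 40 frames at 0.1 µm/px.

## Design choices that were genuinely open

* **One point per filament, $L$ averaged over frames.** Per-frame contour
  estimates vary only by tracking noise for an inextensible filament;
  averaging is the symmetric counterpart of averaging $R^2$, and one pooled
  unweighted fit across filaments treats each filament as one observation.
* **Whole-stack 8-bit conversion.** One affine map for all frames keeps
  intensities comparable across time; per-frame scaling would silently
  reweight frames in bleaching-free data.
* **Independent equilibrium frames** rather than Langevin dynamics (above).
* **Endpoints only for $R$.** Internal-segment subsampling would change the
  estimator; the implemented quantity is the end-to-end distance of the
  whole filament, matching the relation being fitted.
* **Logistic parameterisation for melts.** "Sigmoid" admits several forms;
  the four-parameter logistic with constant baselines is the identifiable
  default, and recovery is validated against synthetic ground truth rather
  than any instrument's proprietary fit.
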