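---
title: "Regularized contour flows: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized contour flows: model, numerics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(contourflow)
```

## The problem

Amoeboid cells move by locally expanding and contracting their boundary.
Given a time-lapse of segmented outlines — per frame an ordered, positively
oriented polyline of `M` points in micrometers at frame interval `dt` —
we want smooth, differentiable contour representations, a way to track
reference points ("virtual markers") between frames, space-time maps
(kymographs) of local boundary quantities, and an automated, threshold-based
catalogue of membrane expansions and contractions. The virtual markers are
coordinates, not membrane molecules: there is no physically distinguished
correspondence between successive outlines, so the correspondence must be
*chosen*, and the choice should be explicit, tunable and violation-free.

## Smooth contours

Each frame is fit by kernel ridge regression (the posterior mean of a
Gaussian process) on the circle. The x and y coordinates are regressed
separately on support angles placed at the normalized secant length of the
polyline (first angle 0; the closing secant is included in the
normalization so the angles embed injectively into `[0, 2π)`). The kernel
is the Poisson kernel

$$P_r(\varphi) = \frac{1 - r^2}{2\pi\,(1 - 2r\cos\varphi + r^2)},$$

normalized to unit integral; it is smooth on the circle, so the fitted
curve has analytic derivatives of all orders — curvature and tangents come
for free, and so do the gradients needed by the flow optimizer.

Hyperparameters, with units and defaults:

* `r` ∈ (0, 1) — kernel scale; the effective bandwidth is roughly `1 − r`
  radians. Too small (wide kernel) underfits and eventually makes the Gram
  matrix numerically singular (reported as an ill-conditioning error); too
  large interpolates segmentation noise.
* `sigma_n` > 0 (μm) — assumed segmentation jitter; the ridge parameter.

By default both are chosen once per track by maximizing the Gaussian-process
marginal likelihood on the first frame (x and y jointly, sharing the
kernel) and reused for the remaining frames; they can be pinned in
`pipeline_config()`. Fitting is deterministic, so a shared choice keeps the
representation consistent along the track.

After fitting, the contour is reparametrized to uniform arc length by
inverting the cumulative speed integral on a dense grid (4096 points) and
refitting at equally spaced support angles; passes repeat until the speed
is uniform to a relative `1e-4` (at most 4 passes). All angles live on
`[0, 2π)` with wrap-around arithmetic; the outward normal is the clockwise
rotation of the unit tangent, so a positively oriented convex boundary has
positive curvature.

## The flow family

The parametrization of a closed curve has a phase freedom. Successive
contours are first *phase-aligned*: the shift `τ` minimizes
`∫‖Φ_{k+1}(θ−τ) − Φ_k(θ)‖² dθ`, scanned on a 512-point grid and refined
locally. If the objective is flat to a relative `1e-9` (a degenerate,
effectively symmetric configuration) the smallest shift is taken with a
warning. Alignment and marker optimization are sequential, not joint.

Markers `θ_k` on `Γ_k` are mapped to `θ_{k+1}` on `Γ_{k+1}` by minimizing

$$H = \underbrace{\frac{1}{N\,\delta t^2}\sum_i \|\Phi_{k+1}(\theta_{k+1,i})
  - \Phi_k(\theta_{k,i})\|^2}_{F\ (\mu m^2/s^2)}
  \;+\; \lambda\, \underbrace{N \sum_i |\Delta\theta_{k+1,i}|^2}_{U}$$

over the *lifted* (unwrapped) target angles, initialized at the identity
map. `U` is bounded below by `4π²` with equality exactly at uniform
spacing, so large `λ` drives the markers toward equidistance while `F`
alone (`λ = 0`) gives each marker its nearest point on the next contour.
Crucially the spacing penalty acts on angles, not on positions in the
plane; this is what keeps the map one-to-one under large deformations. An
entropy-based spacing measure (`cost_S`, mean log gap) is provided as an
alternative diagnostic but does not drive the default optimizer.

Two flows are run per track:

* **global** (`lambda_glo = 1000`): propagated marker trajectories over all
  frames; they stay uniform to well under 1% and define the kymograph
  coordinate system. Any mapping violation here is a hard error.
* **local** (`lambda_loc = 0.1`): re-initialized from the uniform grid
  `ξ_i = 2πi/N` before every transition, so each step is independent of
  history; this flow carries the dynamical quantities.

`N = 400` markers, `λ` values and `dt = 1 s` are the package defaults;
tests and the acceptance script use `N = M ≈ 96–160` (and 500 frames where
the robustness claim says 500), which resolves the synthetic geometries
fully at a fraction of the cost — these sizes are the package's validation
choices, stated here once.

### Optimizer

The discrete objective is minimized by gradient descent with analytic
gradients from the kernel representation. A fixed descent step is hopeless
here: at `λ = 1000` the Hessian of `λU` is a scaled cyclic Laplacian with
condition number of order `N²`, and a fixed stable step would need on the
order of `1e5` iterations per transition. The implementation therefore uses
Barzilai–Borwein step initialization with Armijo backtracking (the fixed
`step0` is the fallback for the first iteration and rejected steps), which
is still plain gradient descent but converges in tens to hundreds of
iterations. Convergence is declared at gradient max-norm `1e-8` (at most
`1e4` iterations); if the objective stalls at machine precision first, the
best iterate is returned with `converged = FALSE`. Mapping violations are
*reported*, never repaired — the non-regularized flow (`λ = 0`) is run with
the same machinery precisely to diagnose them.

The optimizer is validated against an exhaustive search oracle: on `N = 8`
instances the global minimum over a 50-point-per-marker angular grid is
computed exactly by dynamic programming over the cyclic gap chain, and the
descent solution matches within one grid cell for
`λ ∈ {0, 0.1, 1000}`.

## Kymographs

For every transition of the local flow:

* **local dispersion** `LD_i = (1/δt) log(Δθ_{k+1,i}/Δθ_{k,i})` (1/s) —
  the discrete rate of marker-gap stretching; positive in expanding
  regions. Every step satisfies `Σ_i Δθ_{k,i} e^{LD_i δt} = 2π` exactly
  (the target gaps sum to the full circle), which the tests assert row by
  row.
* **local motion** `LM_i = ‖Φ_{k+1}(φ(ξ_i)) − Φ_k(ξ_i)‖/δt` (μm/s).
* **curvature** per frame (1/μm), evaluated directly at the global marker
  angles.

`LD` is defined on *relative angular* gaps, so it differs from the physical
stretching rate `d = ∂v_t/∂s + κ v_n` by the spatially constant term
`(1/δt) log(L_{k+1}/L_k)` (both contours are scaled to `[0, 2π)`).
`continuous_dilation_rate()` computes `d` with the tangential derivative
taken per unit arc length, `∂/∂s = (2π/L) ∂/∂θ` — the form in which the
units close and in which `LD + (1/δt)log(L_{k+1}/L_k) → d` at first order
in `δt` (verified with observed convergence order ≥ 0.9 at
`δt ∈ {0.5, 0.25, 0.125}` on analytic flows). The length-change correction
is exposed separately rather than folded into `LD`.

Row `k` of a flow-derived kymograph covers `[t_k, t_{k+1})`; curvature rows
sit on their own frame. Local quantities are mapped onto the global markers
by periodic linear interpolation (nearest-marker assignment is available
behind a flag). Smoothing is a separable Gaussian, `σ = 3` markers
(periodic axis) × `1` frame (reflective time boundaries), truncated at
`4σ`; total mass is conserved. The kymograph y-axis is the raw coordinate
angle — no re-centering on the leading edge.

## Expansion and contraction detection

Thresholds are computed once per track from the whole smoothed LD
kymograph: `P90` = 90th percentile (linear interpolation between order
statistics) of the *positive* values only; `c_med = P90/3`,
`c_high = 2P90/3`; contraction uses the exact negatives. Values above `P90`
are not discarded — they class as high. Using only positive values and the
90th percentile makes the classification robust to outliers; smoothing
first (the implemented order) suppresses single-cell speckle patterns.

Cells are labeled into five classes; same-sign medium and high cells merge
into connected components under 8-connectivity with periodic wrap in the
marker axis. Components shorter than `min_growth_time = 3 s` (inclusive
frame extent times `dt`) are dropped; growth time is
`(end − onset + 1)·δt`. Events are strict positive local maxima of the
smoothed LD over the periodic 8-neighborhood, flagged when they fall in
medium/high expanding cells.

Each pattern row defines a *slice*: the polygon bounded by the pattern's
global-marker positions on `Γ_k` (traversed forward) and their images under
the local map on `Γ_{k+1}` (traversed backward). Kymograph cell `i` holds a
gap quantity on `[θ_i, θ_{i+1})`, so the slice boundary extends one marker
past the run — with that convention a full-circumference slice on the
circle pair 1 → 1.1 μm reproduces the annulus area `π(1.1² − 1²)` to 0.1%.
Slice areas over `δt` give area growth; the union of slices maps a pattern
back onto the cell trace. The statistics bundle counts simultaneous
high-intensity patterns per frame, the fraction of time with more than two,
activity-restricted LD/LM/curvature distributions, growth-time and
area-versus-growth-time tables, and a circular histogram (36 × 10°) of
event positions relative to the instantaneous center-of-mass velocity,
referenced at each event's frame transition.

## The synthetic generator

`generate_track()` emulates segmented tracks of a *Dictyostelium*-sized
cell: base radius 5 μm, `dt = 1 s`, `M` points sampled at equal arc length
(the output of a well-behaved segmentation), optional isotropic Gaussian
vertex noise (segmentation jitter; 0.01–0.05 μm is realistic for
fluorescence data), one private RNG stream per track seeded from the
recipe. Shapes: static, translating (0.1 μm/s, a typical crawling speed),
uniformly expanding, rigidly rotating ellipse, and a Gaussian radial bump
`r(ψ,t) = R + a(t) e^{−\mathrm{angdist}(ψ,θ_0)^2/(2w^2)}` whose amplitude
ramps linearly (detection fixtures) or oscillates (robustness fixtures; up
to 3 μm on a 5 μm cell — a 60% radial deformation). Ground truth —
curvature, `v_n`, `v_t`, the dilation rate `d`, lengths, and the planted
mask `{ψ : contribution > 0.1 a(t)}` during growth frames — is closed form.

What the generator does *not* emulate: pixelation and optics (no point
spread function or photobleaching), segmentation failures, topology changes,
strongly concave shapes beyond the bump flanks, and biological variability.
Passing tests therefore certify the numerics (geometry, optimization,
transport identities, detection logic) on clean, known-truth inputs — not
segmentation robustness on real microscopy data.

## Numerical choices and degenerate inputs

* Linear solves use Cholesky with an explicit failure path: a singular
  Gram matrix raises an ill-conditioning error naming the remedy.
* Duplicate consecutive polyline points, non-positive orientation and
  self-intersecting recipe parameters are rejected at construction;
  negatively oriented frames read from files are reversed with a warning.
* Phase-alignment ties break toward the smallest shift; degenerate slice
  polygons (< 3 distinct vertices) count zero area with a warning; an
  all-negative LD kymograph is a degenerate-input error for thresholding,
  while an empty pattern list yields an empty statistics bundle without
  error.
* All pipeline outputs are plain text with fixed `%.17g` formatting;
  identical inputs and configuration give byte-identical files.

## Known limitations

* The marker flow is a modeling choice; like every boundary-correspondence
  scheme it does not track physical membrane material.
* `LD` thresholds are per track (by construction), so absolute threshold
  values are not comparable across tracks with different activity levels.
* The local map is interpolated linearly between markers when slicing
  patterns; sub-marker pattern boundaries are resolved only to one marker.
* Hyperparameter selection on the first frame assumes the first frame is
  representative; pin `r` and `sigma_n` when it is not.
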