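# contourflow

Analysis of amoeboid cell-shape dynamics from segmented boundary tracks.

Motile amoeboid cells — *Dictyostelium discoideum* is the classic model —
move by extending localized membrane protrusions (pseudopodia) at the front
and retracting a stable rear (the uropod). `contourflow` turns a stack of
segmented cell outlines (one closed polyline per video frame, micrometers,
typically one frame per second) into:

1. **Smooth periodic contours.** Each polyline is fit by kernel ridge
   (Gaussian-process posterior mean) regression on the circle with a
   Poisson kernel, `P_r(φ) = (1 − r²) / (2π(1 − 2r cos φ + r²))`, with
   support angles placed at the normalized secant length of the polyline,
   then reparametrized to uniform arc length. Curvature, normals, length,
   enclosed area and center of mass follow analytically.
2. **A one-parameter family of regularized marker flows.** `N` virtual
   markers on contour `Γ_k` are mapped to `Γ_{k+1}` by minimizing
   `H = F + λU`, where `F` is the mean squared marker displacement
   (μm²/s²) and `U = N Σ Δθ²` penalizes non-uniform marker spacing
   (minimal, `4π²`, exactly at equal spacing). Large `λ` (default 1000)
   gives the near-equidistant *global* flow that defines a boundary
   coordinate system (after phase-aligning successive contour
   parametrizations); small `λ` (default 0.1) gives the *local* flow,
   re-initialized from the uniform grid at every frame, that carries the
   dynamical signal. `λ → 0` recovers the nearest-point (reversed normal)
   flow. Because the spacing penalty acts on angles rather than positions,
   the flow stays free of mapping violations even under large deformations.
3. **Kymographs.** Per-marker local dispersion
   `LD_i = (1/δt) log(Δθ_target / Δθ_source)` (1/s; positive where the
   boundary expands), local motion `LM_i = ‖ΔΦ‖/δt` (μm/s) and curvature
   (1/μm), resampled onto the global coordinate markers and optionally
   smoothed by a separable Gaussian (3 markers × 1 frame).
4. **Expansion/contraction detection.** The 90th percentile `P90` of the
   positive smoothed-LD values is split into thirds: cells with
   `LD ≥ 2P90/3` are high-expansion, `≥ P90/3` medium; contraction uses the
   mirrored thresholds. Connected space-time components (8-connectivity,
   periodic in the marker axis) lasting at least 3 s become patterns, with
   per-frame slice areas, growth times, event maxima and a statistics
   bundle (simultaneity counts, activity-restricted distributions, circular
   histograms relative to the direction of motion).

A synthetic-track generator (`generate_track()`) produces translating,
expanding, rotating-ellipse and Gaussian-bump-protrusion tracks with
closed-form curvature, velocity decomposition, dilation rate and planted
protrusion masks, so every stage is testable without microscopy data.

## Worked example

```r
library(contourflow)

# a 5 um cell growing a pseudopod-like bump at angle pi/2 (12 s ramp to 2 um)
syn <- generate_track(track_recipe("bump_protrusion", n_frames = 24,
                                   n_points = 150, radius = 5,
                                   bump_angle = pi/2, bump_width = 0.35,
                                   bump_amplitude = 2, t_on = 4, t_off = 16))
res <- run_pipeline(syn, pipeline_config(n_markers = 96), verbose = FALSE)

res$thresholds
#> <activity_thresholds> +/-(0.006803, 0.01361) 1/s (P90 = 0.02041)
res$patterns[[1]]
#> <contour_pattern> #1 expansion: frames 4-16 (growth time 13 s), 234 cells
res$patterns[[2]]
#> <contour_pattern> #2 contraction: frames 11-14 (growth time 4 s), 126 cells
range(res$kymographs$ld$values)
#> [1] -0.007624508  0.033059363
```

The thresholds say: the strongest tenth of the expanding activity on this
track exceeds 0.020 1/s, so cells above 0.0136 1/s are classed
high-activity and cells above 0.0068 1/s medium. The detected expansion
starts at the frame where the planted bump starts growing (frame 4) and its
marker support sits around `π/2` — the planted location; the weaker
contraction pattern is the flanks of the bump pulling boundary inward as
material feeds the protrusion. On a static track the same pipeline returns
an empty catalogue and an all-zero LD kymograph.

The pipeline writes its artifacts (`kymograph_*.txt` matrices,
`patterns.csv`, `events.csv`, `stats_*` files, an `archive.rds` container
and the effective `config.txt`) when `out_dir` is given, and the same steps
are scriptable from a shell via `inst/cli/contourflow`
(`synth | fit | flow | kymo | detect | stats | run`).

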