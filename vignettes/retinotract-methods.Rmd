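---
title: "Methods: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the parameters that
matter, what the synthetic phantom does and does not emulate, and the
numerical decisions taken where the design was genuinely open. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

A white-matter tract connecting the visual thalamus (LGN) to a
retinotopically organized cortical area can be subdivided by where its
streamlines terminate: an anterior (foveal) versus posterior
(peripheral) half of the cortical region, defined along the region's
eccentricity/myelin/thickness gradient. Two operational definitions of
the subcomponents exist — an *automatic* one (endpoint within one half
of the split ROI) and a *manual* one (exclusion planes that remove
dorsally- or ventrally-travelling fibers) — and their agreement is
quantified with signal-detection statistics. The package implements
that entire chain on a synthetic phantom so every stage is testable
without data downloads.

## The diffusion model

Signals follow the single-tensor forward model
\(S(b,\mathbf g) = S_0\,e^{-b\,\mathbf g^\top D\,\mathbf g}\) with
\(D\) symmetric positive semi-definite in mm²/s. Fitting inverts the
log-linearized model by ordinary least squares per voxel over **all**
shells; a weighted variant (weights \(\hat S^2\), one reweighting pass)
sits behind `method = "wls"`. OLS is the default because it is
deterministic, closed-form, and entirely adequate at phantom SNR; the
choice of all shells (rather than one) for the tract-profile scalars is
a documented decision where common practice varies.

Scalars come from the eigenvalues (sorted descending, clamped to zero
for the maps only; raw values stay accessible through
`tensor_eigenvalues()`): MD = mean, RD = mean of the two minor
eigenvalues, FA the usual normalized deviation, defined as 0 for the
all-zero tensor. Diagonal tensors bypass the trigonometric closed form
and are solved exactly, so a pure stick has FA exactly 1. Signals at or
below zero are floored to machine epsilon before the log.

## The phantom: a stated world

The generator's defaults *are* the conditions the tests assume:

| parameter | default | why |
|---|---|---|
| grid | 40 × 48 × 40 voxels, 1 mm isotropic | smallest grid that holds both arcs with margin |
| bundles | 2 × 200 streamlines, 60 points | "400 labelled streamlines" is the stated test world |
| bundle separation | 12 mm | dorsal/ventral arcs clearly separated at the apex, shared corridor near the ROIs |
| jitter | σ = 0.6 mm radial, constant per streamline | tube-like bundles ~2–3 voxels thick |
| acquisition | b = 1000/2000/3000 s/mm², 30 directions/shell, 6 b0 | HCP-like multi-shell at desk scale |
| SNR | 30 (b0 over σ) | typical preprocessed dMRI; Rician by default |
| corridor tensors | dorsal λ = (1.7, 0.3, 0.3)·10⁻³, ventral λ = (1.4, 0.45, 0.45)·10⁻³ mm²/s | white-matter-like; same MD, distinct FA, so the two subcomponents have genuinely different FA profiles (the dorsal component is the more anisotropic one, as reported for the real tract) |
| other white matter | isotropic 0.8·10⁻³ mm²/s | deep-matter background |

Geometry: RAS world coordinates; the first axis is medial→lateral, the
second posterior→anterior, the third inferior→superior; voxel centers
sit at `affine · (i, j, k, 1)` with 0-based indices. Bundle centerlines
are cubic Béziers (4 control points each): the dorsal bundle starts in
the medial half of the seed ROI, arcs over a carved "ventricle" void in
the white-matter mask, and terminates in the anterior half of the
target ROI; the ventral bundle runs low from the lateral seed half to
the posterior target half. The target ROI carries a strictly monotone
anterior–posterior linear gradient standing in for
eccentricity/myelin/thickness maps.

What the phantom does *not* emulate — and what a green test therefore
does not establish: crossing or kissing fibers, partial-volume cortex
and CSF, susceptibility or motion artefacts, inter-subject anatomical
variability, nonlinear registration error. The phantom validates the
*logic* of the chain (geometry, classification, statistics,
bookkeeping), not robustness to real-data pathology.

Noise is Rician (magnitude of a complex Gaussian with
σ = S0/SNR), matching magnitude MRI; a Gaussian mode exists because
its noise standard deviation is analytically checkable. `snr = Inf`
returns the exact forward model, which the fit-recovery tests rely on.

## Tracking

Deterministic tensor-line tracking: seeds drawn uniformly inside the
seed mask (voxel uniform, then uniform within the voxel cube, all from
a named seed), bidirectional propagation along the principal
eigenvector of the tri-linearly interpolated tensor, eigenvector sign
aligned with the previous step. Step size defaults to half a voxel.
The curvature values are *radii* in mm (the legacy convention of the
tracking tool the protocol names); each converts to a per-step bend cap
θmax = 2·asin(step/(2r)) — radius 1 mm at step 1 mm gives exactly 60°,
and radii at or below step/2 leave the angle unconstrained.
Termination: leaving the white-matter mask, interpolated FA below
`fa_threshold` (default 0.1, the standard tensor-tracking cutoff; this
also implements the "all-isotropic field → empty result plus warning"
contract), the bend cap, or the length window. Acceptance requires
passing within 2 mm of *both* ROIs and both endpoints within 2 mm of
the ROI union — the operational reading of "seed masks were also used
as endpoints". The ensemble merges the per-radius runs by plain
concatenation (merged, not deduplicated), keeping per-radius
provenance.

The published budget of 10,000 fibers over 1,000,000 trials per radius
remains the `tracking_config()` default; `default_run_config()` caps a
pipeline run at 200 fibers / 2,000 trials per radius because the
phantom's two bundles saturate far below the published budget and the
full default pipeline should run in well under a minute.

## Streamline evaluation (pruning)

A deliberate reduction of linear fascicle evaluation: each candidate
contributes, in every masked voxel it traverses, a stick-model
demeaned signal \(e^{-b(\mathbf g^\top \mathbf t)^2 d_{ax}}\) (local
mean tangent \(\mathbf t\), axial diffusivity
d_ax = 1.7·10⁻³ mm²/s, one shell — the lowest b by default), scaled by
the voxel's mean b0. Non-negative least squares against the equally
demeaned measured signal yields per-candidate weights; candidates
above 10⁻⁸ of the maximum weight are kept. No isotropic compartment,
no multi-shell kernel: faithful in spirit, small enough to test
exhaustively.

Solver: small problems (≤ 64 candidates) use the classical
Lawson–Hanson active-set method; larger ones use block principal
pivoting, because the near-collinear columns produced by ensembles of
near-duplicate streamlines make one-at-a-time active-set pivoting
cycle for thousands of iterations while block pivoting reaches the
same optimum in tens. Both are checked against a brute-force
subset-enumeration oracle on small instances. At the optimum the
weight *vector* need not be unique (collinear columns); the
*prediction* is, which is what the tests assert.

## Subdivision and statistics

`split_roi()` takes the first principal direction of the ROI voxel
centers as the major axis (sign-aligned with an orientation hint so
"anterior" is positive), orders voxels by projection with ties broken
by voxel index, and assigns the upper ⌈n/2⌉ to the anterior half —
deterministic, enumeration-order invariant, off by at most one voxel.
Degenerate ROIs (no unique principal direction, e.g. a ball) fall back
to the hint axis.

`classify_by_endpoint()` tests the endpoint nearer the ROI: within
2 mm of anterior voxel centers only → PRO1, posterior only → PRO2,
both → the nearer half (ties anterior), neither → UNASSIGNED. The 2 mm
criterion is inclusive and measured to voxel *centers*, matching the
coordinate-list semantics of the tool the protocol names; the general
any-point intersection lives in `intersects_roi()`, endpoint-specific
logic here.

`detection_stats()` computes d′ = z(hits) − z(false alarms) with R's
`qnorm` (inverse-normal accuracy far beyond the 10⁻⁹ requirement).
Rates of exactly 0 or 1 are clamped to 1/(2N) — the standard
correction that keeps d′ finite — which is why perfect phantom
separation reports d′ ≈ 5.4 at N ≈ 150 rather than infinity.

`endpoint_histogram()` sorts seed-ROI voxels by world X (medial →
lateral) and counts streamlines whose seed-side endpoint lies within
2 mm of each voxel center; one endpoint may contribute to several
voxels, as per-voxel counting implies.

## Maps and profiles

Density maps count *distinct* streamlines per voxel (each resampled at
half-voxel spacing; loops count once) and normalize by the maximum
count, so the map peaks at exactly 1. Smoothing is a separable
Gaussian with σ = FWHM/(2√(2 ln 2)) in mm converted per axis to voxel
units; kernels are normalized to unit sum (mass conserved away from
the boundary, zero padding at it); sheared affines are rejected rather
than silently mishandled. Consistency maps smooth each subject's
density map *then* binarize (> 10⁻⁶, so the smoothed support defines
presence) — the source protocol's sentence order is ambiguous on this;
smoothing-first is adopted and flagged. In the single-phantom pipeline
the five per-radius tracking passes stand in for "subjects"; the API
accepts any list of per-subject tractograms in a common space.

Tract profiles reorient streamlines by nearest-endpoint matching to
the first streamline (an unstated but necessary step for node-wise
averaging; deterministic), resample each to 100 equal-arc-length
nodes, sample the scalar maps tri-linearly, and average per node,
Gaussian-weighted by distance to the per-node coordinate mean
(σ = the node's coordinate standard deviation) by default, uniformly
on request. Per-node spacing is reported so inter-node distances are
derivable.

## Numerical notes

* **Resampling idempotence.** Arc-length resampling is exactly
  idempotent on equal-segment polylines. On curved polylines a second
  application moves nodes at the order of the discretization error
  (~10⁻⁵ mm on a 200-point quarter circle) because equal arc spacing
  along the input does not produce equal chord spacing of the output;
  the map converges quadratically to its fixed point, which the tests
  pin below 10⁻⁹ mm. No implementation of this standard algorithm can
  satisfy literal one-step idempotence at 10⁻⁹.
* **Eigen-decomposition.** Vectorized trigonometric closed form for
  the R-side scalar maps with an exact path for diagonal tensors;
  cyclic Jacobi in the compiled tracker. FA rotation invariance holds
  below 10⁻¹⁰.
* **Determinism.** Every stochastic step draws from a named seed
  through a save/restore helper; the tracker consumes pre-generated
  seed points in chunks whose size cannot affect the draw sequence;
  identical configurations produce byte-identical classification CSVs.
* **Error taxonomy.** Usage (exit 2), format (3), and model (4) errors
  are distinct condition classes; the pipeline aborts with the failing
  stage named and all artifacts up to the failure preserved.

## Known limitations

Single-compartment tensors cannot represent crossings, so the tracker
is only as good as the phantom is simple. The LiFE reduction scores
orientation consistency on one shell; it will not reproduce published
full-kernel weights on real data. TRK support targets the v2
voxel-mm/corner-origin dialect; exotic header variants are rejected
rather than guessed. The manual/automatic comparison on the phantom is
an upper bound on agreement — real tracts disagree more.
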