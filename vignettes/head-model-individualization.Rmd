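---
title: "Statistical shape models for M/EEG head-model individualization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape models for M/EEG head-model individualization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcawarp)
```

## The problem

Boundary-element (BEM) forward models for EEG and MEG source localization
need the geometry of the nested tissue boundaries — scalp, skull,
cerebrospinal fluid (CSF) and cortex — of the individual subject. When no
structural MRI or CT is available, practitioners fall back on template heads,
which can misplace sources by centimetres. What *is* often available is a
partial view of the outer head surface: a photogrammetry scan, or digitized
electrode positions. This package estimates a subject's full four-shell head
geometry from such a **scalp proxy** by fitting the weights of a statistical
shape model learned over a population of consistently meshed heads, so that
the hidden surfaces (skull, CSF, cortex) follow from their statistical
coupling with the visible scalp.

## The shape model

Every head is a `head_model`: four `surface_mesh` shells sharing one
triangulation with `V` vertices (the database convention is `V = 1922`,
giving `2V - 4 = 3840` triangles per closed genus-0 shell), plus the
fiducials NAS, LPA and RPA. All geometry lives in the CTF head frame (origin
midway between LPA and RPA, x toward NAS, ALS orientation, millimetres),
which any subject can be brought into by measuring the three fiducials.

`flatten_head()` concatenates the shells (scalp, skull, CSF, cortex, each
vertex as x, y, z) and the fiducials into a shape vector of length
`12 V + 9` — 23064 mesh coordinates plus 9 fiducial coordinates = 23073 at
the standard resolution. `fit_shape_model()` centres the population's shape
vectors per coordinate and extracts principal components as the top
right-singular vectors of the centred data matrix. The SVD is taken directly
(no `D x D` covariance is ever formed; `D` is tens of thousands while `n` is
tens to hundreds). Because all coordinates share millimetre units, the
default normalization is centring only; per-coordinate variance scaling
(`normalization = "zscore"`) is available but off by default, since it would
inflate the influence of low-variance coordinates.

A head is reconstructed as `mean + sum_j w_j PC_j` (`reconstruct_head()`),
with **one scalar weight per component**. The projection of a known head onto
the leading components is the closed-form inner product
(`project_weights()`), exact by orthonormality; reconstruction of a training
head from all components is exact to numerical precision, which the test
suite asserts at `1e-6` mm.

## Fitting a scalp proxy

`fit_pcawarp()` minimizes, over the first `n_pcs` PC weights,

```
sum_k d(proxy_k, scalp(w))  +  lambda * g(head(w))
```

where `d` is one of two metrics and `g` is an inter-shell proximity penalty.

**Vertex distance** takes each proxy point's distance to the nearest scalp
mesh vertex. It is simple but meshing-dependent: it mixes true surface
distance with the tangential offset to wherever the nearest vertex happens to
sit.

**Shape difference** (the default) casts a ray from the head centre — the
mean cortex vertex, a robust stand-in for unreliable surface normals on
distorted intermediate meshes — through the proxy point, intersects it with
the scalp mesh, and takes the distance from the proxy point to that
intersection. It measures error approximately normal to the surface and is
insensitive to the triangulation. Correspondences (nearest vertices or ray
intersections) are recomputed at **every** objective evaluation. Rays that
miss (a momentarily non-star-shaped mesh) fall back to the vertex distance
for that point and are counted.

**The penalty** `g` sums, over all unordered pairs of distinct shells and all
vertex pairs closer than a threshold `T`, the shortfall `T - distance`. It
keeps the optimized shells from touching or crossing, which would make them
useless for BEM. `T = 1` mm by default. Each unordered pair is counted once
(a double sum over ordered pairs would only double the penalty, a constant
factor absorbed by the weight `lambda`, default 1). The penalty is active for
both metrics and can be switched off with `penalty_weight = 0`. The data term
uses unsquared Euclidean norms by default; a squared variant is available
(`squared = TRUE`) and is smoother, at the price of down-weighting small
residuals.

**Optimizer.** The objective is piecewise-smooth (correspondences switch
along the way), so it is minimized by BFGS with central finite-difference
gradients, starting from the mean head (zero weights), with one restart from
the best-seen iterate if the first run stalls above it. Weights are
parameterized internally in units of their singular values so the optimizer
sees comparably scaled axes; results are reported in raw units. The best
iterate is always returned; hitting `max_iter` flags `converged = FALSE`
without raising. A fast mode (`method = "frozen"`) alternates freezing the
correspondences with an exact linear least-squares solve; with frozen
correspondences and the vertex-distance metric the data term is a linear
least-squares problem, which the tests exploit as an oracle.

Defaults worth knowing: `n_pcs = 16` (a good compromise between accuracy and
scalp overfitting — see below), `tol = 1e-6` relative objective tolerance,
`max_iter = 60`. Proxies are CTF-aligned via their own fiducials before
fitting; the fiducials take no part in the data term, and the reconstructed
head carries the shape model's fiducials.

**Proxy preprocessing** (`preprocess_proxy()`) mirrors the standard workflow
for photogrammetry scans: CTF alignment, a cut 35 mm above the fiducial
plane (ears, neck and face removed; ties at the offset are kept so the
boundary is deterministic), and farthest-point decimation to a target count
(default start: the point farthest from the centroid, removing any seed
dependence). For digitized electrodes on holders, `move_inward()` shifts
positions along outward normals (12 mm is typical holder thickness);
area-weighted vertex normals are computed when none are supplied.

## The TPS baseline

`warp_headmodel()` re-implements, in spirit, the classical template-warp
individualization: raytraced correspondences from the template cortex
centroid to each proxy point (the same construction as the shape-difference
metric, chosen for a fair comparison — the original publications do not pin
down the correspondence rule), a 3D thin-plate spline (`U(r) = r`) fitted on
those pairs, applied to all four shells and the fiducials. Regularization
defaults to `1e-6` times the median control spacing to stabilize
near-coplanar electrode layouts. The warp interpolates the proxy exactly at
zero regularization, so a proxy sampled from the template reproduces the
template — a property the acceptance tests assert at `1e-6` mm. Because the
warp can only deform the template, inner shells inherit template detail, and
spiky proxies can produce distorted, nesting-violating heads; `check_nesting()`
is run on every result and violations are reported.

## The synthetic population

Real head databases are built from segmented MRIs and cannot be shipped.
`generate_population()` is a first-class, tested stand-in that emulates the
*output conventions* of such a database: per head, four nested star-shaped
shells on a shared reference triangulation, CTF-aligned, with correlated
shape variation across tissues so that inner surfaces are predictable from
the scalp — the property the whole method rests on.

The generative model for head `i`, tissue `t`, direction `u`:

```
r_ti(u) = base_t(u) * (1 + sum_f loadings[t, f] * amp_f * z_if * mode_f(u)) + noise
```

* `base_t`: anisotropic ellipsoid radial functions with strictly decreasing
  radii (default 100/95/90/85 mm and axis scales 1.05/0.95/1.00 — a slightly
  elongated, realistic head; the anisotropy is fixed, not sampled, so the
  latent dimension is exactly `k`).
* `mode_f`: smooth directional basis functions (real spherical-harmonic-like
  polynomials up to degree 3, deterministic order, unit RMS). They are
  corrected to vanish at the fiducial directions (+x, ±y), which keeps every
  noise-free head *exactly* CTF-consistent and the flattened coordinates
  *linear* in the latent scores — so a noise-free population has matrix rank
  exactly `k`, which the tests assert.
* `loadings`: default `(1.0, 0.9, 0.85, 0.8)` from scalp to cortex for every
  factor — inner shells co-vary strongly with the scalp, mirroring the
  real-database assumption that makes scalp-based inference of hidden
  surfaces possible. The cortex/scalp loading ratio is recovered from the
  generated meshes by regression in the tests.
* `amp_f`: default 0.015 per factor (~1.5% radial modulation per unit latent
  score, i.e. a few millimetres of scalp variation — the realistic
  inter-individual scale).
* `noise`: independent Gaussian radial perturbation per vertex (mm). Noisy
  heads get their fiducials re-measured by raytracing and are re-aligned to
  CTF. Heads violating shell nesting are rejected and resampled (clipping
  would distort the stated latent distribution); the count is reported.

`sample_scalp_proxy()` emulates the two acquisition modes: area-weighted
uniform sampling of the scalp above the ear plane with isotropic noise
(photogrammetry), and a deterministic ring-and-arc layout with exact point
counts (electrodes; 21/64/343 points approximate the 10-20/10-10/10-5
densities).

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: gyral/sulcal cortical detail, skull-base and jaw
anatomy, demographic covariates, segmentation artifacts, and — importantly —
the high effective latent dimensionality of real head shape. Its residual
detail is *iid vertex noise*, which is statistically orthogonal to any
training population. One consequence is visible in the overfitting analysis
below.

## Evaluation harness

`shape_error_report()` scores a fitted head against a ground-truth head per
tissue in both metrics (shape difference measured along rays from the truth
cortex centroid); `per_vertex_error_map()` returns per-vertex shape
differences with a display cap (default 11 mm, raw values retained).
`loo_curve()` and `sweep_table()` run leave-one-out analyses over component
counts and proxy sizes; `n_pcs = 0` rows are the mean-head baseline by
definition.

The source-localization harness works at desk scale: an analytic closed-form
potential for a current dipole in a homogeneous conducting sphere with
insulating exterior (`sphere_forward()`, average-referenced; validated in the
tests against a truncated Legendre-series solution to `1e-8` relative error)
replaces the numerical FEM/BEM solvers of a production pipeline, which are
explicitly out of scope — any function returning an electrodes-by-3 gain
matrix can be plugged in instead. `dipole_fit_linear()` scans a regular
source grid (placed inside the cortex mesh by ray-parity at 10 mm spacing by
default), solving each position's moment by linear least squares and ranking
by residual variance `RV = sum((x - xhat)^2) / sum(x^2)`; ties go to the
lowest grid index. `dipole_fit_nonlinear()` refines position locally
(Nelder-Mead; the moment is re-solved at every position), never returns a
worse RV than its start, and reports an aborted fit with `RV = 1` by
convention. Noise injection for simulation studies uses the *power* ratio
definition of SNR (noise variance = signal power / SNR); an amplitude-ratio
convention would simply square the factor, and either can be implemented by
scaling the noise standard deviation. `compare_models()` runs one-sided
paired Wilcoxon signed-rank tests over every ordered model pair with
Benjamini-Hochberg correction across pairs; when fits are discarded (aborted
dipole fits), they should be discarded for all models jointly.

## Numerical choices

* Ray-triangle intersection: Möller-Trumbore with a `1e-12` determinant
  epsilon and `1e-9` barycentric tolerance; only strictly positive ray
  parameters count; ties between coincident hits go to the lowest triangle
  index; degenerate triangles are skipped. For star-shaped meshes with a
  shared ray origin, triangles are pre-filtered by an angular cone around
  each triangle's centroid direction; any pruned miss falls back to the full
  scan, so results are identical to the exhaustive scan (asserted against a
  brute-force oracle in the tests).
* The inter-shell penalty uses an exact uniform-grid neighbour search with
  cell size `T`; the tests compare it with the `O(V^2)` double loop.
* The reference sphere is a latitude/longitude triangulation with the poles
  on ±z, chosen because it realizes *exactly* `V` vertices and `2V - 4`
  triangles for any `V` whose `V - 2` factorizes into a ring grid (both 1922
  and the reduced test resolution 642 do). Icosahedral refinements only
  realize `V in {12, 42, 162, 642, 2562, ...}`. A published triangle count of
  3990 for `V = 1922` is inconsistent with Euler's formula for a closed
  genus-0 surface (`2V - 4 = 3840`); this package uses closed meshes with
  `2V - 4` triangles.
* CTF axes: `x = unit(NAS - midpoint(LPA, RPA))`,
  `z = unit(x × (LPA - RPA))`, `y = z × x`. NAS lands exactly on +x and LPA
  on +y (ALS).
* Shape-vector tissue order is fixed: scalp, skull, CSF, cortex, then NAS,
  LPA, RPA — outermost first, matching the fitting flow.

## Problem sizes

The shipped analyses are scaled to run on a single CPU in minutes: the
synthetic study population is 60 heads with `k = 8` latent factors at
`V = 642` and 0.3 mm vertex noise; leave-one-out fits use a 343-point
noise-free photogrammetry proxy with 8 components (the latent dimension);
the proxy-size comparison uses 21/64/343 points at 10 components over 10
sampling seeds; the overfitting comparison fits 50 versus 8 components on 16
folds at a deeper convergence setting (`max_iter = 100`, `tol = 1e-6`); the
dipole study uses 64 electrodes on the upper hemisphere of an 85 mm sphere
and a 10 mm grid, with Monte-Carlo truth sources drawn from the
montage-covered upper region (neocortex-like; EEG cannot localize sources
below its montage) while the linear search scans the full grid. `scripts/acceptance.R` re-runs all of it from scratch and
writes the resulting numbers as JSON.

## The overfitting analysis, and a caveat

With many more components than the data support, the fit chases the proxy:
the scalp-proxy residual keeps dropping while the hidden surfaces get
*worse* — the model buys proxy fit with unconstrained inner-shell movement.
The acceptance analysis measures exactly this signature on identical folds:
the median scalp-proxy residual (50 versus 8 components, sign test across
folds) and the cortex shape difference against the hidden truth.

A caveat specific to the synthetic world: the *full-surface* scalp error
against the noisy truth does not improve with extra components here, unlike
in populations of real heads. With iid vertex noise and latent dimension
`k = 8`, components beyond 8 carry only training-noise directions, so they
can tighten the fit at the 343 sampled points but wiggle arbitrarily between
samples and below the ear cut. Real anatomy behaves differently because
individual scalp detail largely lies in the span of a large training
population. Both quantities are computed and reported by the acceptance
script (`overfit_proxy_residual_decrease_folds`,
`overfit_fullscalp_decrease_folds`) so the distinction stays visible.

## Known limitations

* The generator's anatomy is star-shaped and smooth; none of the hard cases
  of real segmentation (ears, nose, jaw, brainstem exit) exist in it.
* The single-sphere forward model exercises the fitting machinery only;
  absolute localization errors in it say nothing about four-shell BEM
  accuracy.
* The TPS baseline is a re-implementation in spirit; the original toolbox's
  correspondence and regularization choices are not published in detail.
* `"Linear regression"` style fitting of the weights is only exactly linear
  with frozen correspondences; the shipped default is the nonlinear BFGS
  path, and the frozen mode is an approximation that ignores the penalty
  during its solves.
* Conductivities (`tissue_conductivities()`: scalp 0.465, skull 0.010, CSF
  1.65, cortex 0.201 S/m) are carried as constants for downstream use; no
  forward solver in this package consumes the four-shell values.
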