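---
title: "Methods: keratin network morphometry, motility and cell mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: keratin network morphometry, motility and cell mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keranet)
```

keranet quantifies three aspects of the keratin intermediate filament
system in cultured epithelial cells: the geometry of the filament network
(branch lengths), its dynamics (inward transport and assembly/disassembly
turnover), and the mechanical phenotype of the cell (indentation stiffness
and cytoplasmic creep compliance). Because raw microscopy and force data
are rarely redistributable, every analysis stage is paired with a seeded
synthetic generator that produces inputs with known ground truth; the test
suite validates each stage against that truth and against independent
brute-force oracles.

## Branch-length morphometry

The morphometry pipeline converts a fluorescence image of the keratin
network into a geometric graph and measures the filament length between
branch points:

1. **Gaussian denoising** (`gaussian_denoise()`, default sigma 1 px) —
   plain separable convolution with reflective boundaries.
2. **Curvilinear enhancement** (`oof_filter()`) — the optimally oriented
   flux: at each pixel and probe radius $r$ the symmetric matrix
   $Q_{ij}(x;r)$ collects the outward flux of the image gradient projected
   on direction $i$ through the circle of radius $r$, normalized by the
   circle's boundary measure. Bright tubular structures produce one
   strongly negative eigenvalue transverse to the filament, so the
   response is $\max(0, -\lambda_{\min})$, maximized over radii. The
   matrix entries are computed by spectral-domain convolution with the
   analytic multiplier $-u_i u_j J_1(r|u|)/|u|$, which makes the filter
   rotation invariant (the spatial alternative of sampling interpolated
   gradients on the circle is anisotropic at the few-percent level; it
   survives as the independent oracle in the tests). Default radii
   $\{1, 2, 3, 4, 6, 8\}$ px bracket keratin bundle widths at the standard
   0.0775 µm/px sampling. The image is treated as periodic; structures
   should stay clear of the border by the largest radius.
3. **Thresholding** (`binarize()`) — Otsu by default (fixed threshold as
   an override); a constant response is rejected as degenerate rather
   than silently thresholded.
4. **Thinning** (`extract_centerline()`) — Zhang–Suen two-subiteration
   morphological thinning, preserving 8-connectivity topology.
5. **Graph reconstruction** (`reconstruct_graph()`) — skeleton pixels are
   classified by neighbour count (1 = endpoint, ≥ 3 = branch voxel) after
   removing *redundant diagonal links* (a diagonal neighbour already
   reachable through a shared orthogonal neighbour). Without that pruning
   every crossing of two skeleton arms spawns a cluster of spurious
   junctions. Paths between node pixels become polyline edges in
   micrometres (voxel centres at integer coordinates, physical position =
   index × spacing); node-free cycles become self-edges.
6. **Branch-point merging** (`merge_branch_points()`, default radius
   2 px) — thinning can leave a physical branch point as several adjacent
   branch voxels; branch nodes within the Chebyshev radius are
   single-linkage clustered to their centroid and residual stubs deleted.
   Degree conservation (sum of degrees = 2 × edge endpoints) is asserted
   in the tests after every transformation.
7. **Geometric low-pass** (`smooth_polylines()`, default window 5) — a
   centred moving average over interior polyline vertices with pinned
   endpoints. A staircase rasterization of a diagonal overestimates length
   by $\sqrt2$; smoothing brings it within ~2% of the true diagonal.
8. **Branch lengths** (`branch_lengths()`) — by default only edges whose
   both ends are branch points enter the distribution ("length between
   branch points"); endpoint-terminated edges are kept under a separate
   label. Edges shorter than 3 px equivalents are pruned as thinning
   artifacts.

**What passing tests show.** On noise-free single filaments ≥ 10 µm the
pipeline recovers length within 5% (the residual error is tip erosion by
thinning plus smoothing). On sparse branched phantoms the recovered mean
branch length tracks the generator truth within 10% *when a common 1 µm
length floor is applied to both sides*; edges at the optical resolution
limit (a few pixels) are dominated by spur/stub bookkeeping on both sides
of the comparison and are not meaningful measurements. Dense networks
where independent filaments cross are fragmented at the crossings — the
image genuinely contains those junctions while the ground-truth graph does
not — so absolute branch-length recovery is only validated on sparse
phantoms, and on real data the statistic should be read as an *image*
property, comparable across conditions imaged alike.

## Keratin motility and turnover

`estimate_flow()` computes motion between consecutive frames by
normalized cross-correlation block matching (default 16 px templates on an
8 px grid, search radius 8 px) with 2D quadratic subpixel refinement,
correlation ties broken toward the smaller displacement, vectors
invalidated below a correlation of 0.3, and an optional 3×3 vector-median
filter. On integer shifts the estimator is exact to ≤ 0.25 px. Speeds are
reported in px/min — the "arbitrary units" of a camera pixel — with the
µm/min conversion factor carried alongside (0.0775 µm/px, 30 s frame
interval by default).

`bulk_flow()` computes the turnover (source/sink) map: with keratin mass
taken proportional to fluorescence, the previous frame is pulled back
along the flow (inverse warp, bilinear) and subtracted from the next
frame; the averaged residual, scaled to intensity/min and masked to the
cell, is positive where keratin assembles and negative where it
disassembles. Pull-back warping was chosen over forward splatting to
avoid hole artifacts. The map is regularized with a 2 px Gaussian —
below the width of coherent assembly/disassembly zones, above the pixel
scale at which block-matching jitter otherwise inflates the gross
|assembly| + |disassembly| sum. `summarize_dynamics()` reports the mean
speed over valid vectors and the total bulk flow, defined symmetrically
as (total assembly + total disassembly)/2 per minute, since sources and
sinks balance in steady state.

`normalize_cell()` maps each cell onto a standard disk: pixel $(r,
\theta)$ about the mask centroid is sent to $(r/R(\theta) \cdot R_0,
\theta)$, with the boundary radius $R(\theta)$ sampled along 360 rays.
This requires the mask to be star-shaped about its centroid; a crescent
fails with a diagnostic. Normalized maps from different cells superimpose
pixel-wise (`aggregate_cells()`), with a count map recording coverage.

## Cell mechanics

**Indentation.** Approach curves are modelled as a baseline line followed
by the power law $F = A\,\delta^b$ with $\delta$ in metres and $A$ in the
N/m² convention (so $A = 111$ N/m² at $b = 1.8$ predicts
$111 \cdot (5\times10^{-7})^{1.8} \cdot 10^9 = 0.51$ nN at 500 nm — the
printed force-to-depth identity at one decimal is 0.5 nN). The contact
point is detected from a persistent exceedance of the baseline by
3 baseline-noise SDs and refined with a two-segment least-squares model
(baseline line, then $A(z - z_c)^b$ with the breakpoint free) — a pair of
straight segments cannot localize a power-law onset, which rises too
slowly from zero. Fitting is nonlinear least squares in linear space
(uniform weights) initialized from the log–log fit; with a fixed exponent
the stiffness has the closed-form least-squares solution. Only data up to
the 1.5 nN setpoint enter the fit. Synthetic recovery suites fit with the
generation contact (curves are generated in indentation coordinates), as
with instrument-exported indentation data; contact *detection* has its own
accuracy tests (≈ 11 nm MAE at 2% noise).

**Creep.** Bead tracks under rectangular force pulses (5 s on in a 10 s
period, 50 frames/s) are segmented into peaks; each peak is normalized by
the instantaneous force, $J(t) = (x(t) - \text{baseline})/F(t)$, with the
baseline the mean position over the 0.5 s before onset, and fitted to
$J(t) = J_0 (t/t_0)^\beta$ with $t_0 = 1$ s over $t \in [0.1, 5]$ s (the
first 0.1 s excluded as tracking transient). The default fit is log–log
least squares with the standard log-normal retransformation
$\exp(s^2/2)$ applied to $J_0$; without it, multiplicative tracking noise
biases $J_0$ low by $e^{-\sigma^2/2}$, which at 5% noise already exceeds
the Monte-Carlo 2-SEM band of a 67-peak average. A linear-space nonlinear
fit is available as `method = "nls"`. $J_0$ is interpreted as compliance
in µm/nN at $t_0$; $K_0 = 1/J_0$ is the equivalent stiffness.
`average_creep()` reports per-group means with SEM and the pointwise mean
of rescaled peaks $J(t)/J_0$ with an SD band.

## Statistics

All group contrasts use the two-tailed Mann–Whitney(-Wilcoxon) test
(`mann_whitney()`, backed by `stats::wilcox.test`): exact when both
samples have ≤ 8 tie-free observations, otherwise the normal approximation
with tie and continuity correction. The tests cross-check both modes
against full enumeration of all labelings. Descriptive summaries use
linear-interpolation quantiles (type 7), stated in the report metadata;
no multiple-testing correction is applied, matching single planned
contrasts per quantity.

## The synthetic generators

* **Filament phantoms** — persistent random walks (turn SD
  $(1-p)\,\pi/3$ per 1 px step), branching as a Poisson process along arc
  length, children inheriting half the remaining arc budget, rasterized
  with a Gaussian cross-section (default 1.5 px) so a filament centreline
  reaches the nominal peak intensity. The ground-truth graph records every
  node and polyline exactly.
* **Transport phantoms** — a static textured intensity field inside a
  circular cell advected inward each frame (semi-Lagrangian backtrace with
  bilinear sampling, the same interpolation the turnover estimator
  inverts), default speed profile $1.5\rho^2$ px/frame (peripheral
  maximum, zero at the centre), an assembly annulus at normalized radii
  0.70–0.95 (+3 intensity/min) and a disassembly annulus at 0.15–0.40
  (−3 intensity/min). Note that semi-Lagrangian *value* advection is not
  mass-conservative under a converging profile (it solves
  $\partial_t I + u\cdot\nabla I = 0$, not the continuity equation);
  conservation holds exactly in the motion-compensated sense used by the
  turnover estimator, and in the classical flux-balance sense on the
  uniform-translation debug mode, and the tests assert precisely those
  two statements.
* **Force curves and bead tracks** — as described above, with
  multiplicative noise on the physical signal and additive noise on the
  baseline/tracking channels. Off-pulse bead relaxation is exponential
  with a 0.5 s time constant: long relaxation tails would leak a residual
  of the previous peak into the next pulse's baseline window, breaking the
  generator's own guarantee that noise-free on-pulse displacement equals
  $F J_0 (t/t_0)^\beta$ for every pulse.
* All generators draw from one explicitly seeded RNG per call
  (`withr::with_seed`), leaving global RNG state untouched; fixed seeds
  give bit-identical output.

**What the phantoms do not emulate:** point-spread-function anisotropy
and z-blur, photobleaching, intensity-dependent (Poisson) noise, nuclei
and organelle occlusion, cell-shape changes over the recording, and
filament bundling where intensity is not proportional to mass. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimators under the stated noise models, not performance on arbitrary
microscopy data.

## Numerical choices and problem sizes

Tolerances: noise-free inversions are asserted to 1e-6–1e-9; stochastic
recovery suites use 200 force curves, 67–108 creep peaks, and 6–20
phantom seeds, sizes chosen to keep the whole suite under a minute while
leaving the Monte-Carlo bands well below the asserted tolerances. Flow
phantoms are 128–192 px with 4–8 frames; morphometry phantoms 128–240 px.
Degenerate inputs fail loudly (empty masks, constant Otsu input,
all-baseline curves, zero-force pulses) rather than returning silent
zeros, except where the empty case is scientifically meaningful (an empty
image analyzes to an empty graph).

## Known limitations

* 2D only: z-stacks and 3D thinning are not implemented.
* The OOF filter's periodic boundary treatment can create rim responses
  for structures touching the border.
* "Total bulk flow" has no unique operational definition in the
  literature; the symmetric (assembly + disassembly)/2 convention is this
  package's documented choice.
* Intensity calibration to absolute keratin mass is outside the scope;
  turnover rates are in camera intensity units per minute.
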