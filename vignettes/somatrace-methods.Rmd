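---
title: "somatrace: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somatrace: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

somatrace reconstructs sparsely labeled neurons from 3D lightsheet-style
volumes and scores the resulting skeletons against gold standards.  This
vignette explains the models behind each stage, the parameters that
matter, the numerical choices made where the design was genuinely open,
and what the synthetic phantoms do and do not demonstrate.

## The working-set view

The pipeline is organized around three nested views of the same volume:

* `W` — the dense voxel grid (everything the camera recorded);
* `W_s` — the spatially sparse foreground: voxels above an intensity
  threshold chosen to hit a target foreground percentage;
* `W_c` — the causally sparse subset of `W_s` reachable from detected
  somas (the seeds `{S}`).

Each stage narrows the set that later stages must touch: enhancement
operates on `W`, seed detection on `W_s`, skeletonization only on `W_c`.
The containment `|W_c| <= |W_s| <= |W|` holds by construction and
`working_set_report()` prints the achieved reductions.  Note that when
optional branch closing is enabled, `|W_s|` is counted on the closed
mask the sweep actually runs on.

## Image enhancement

**Destriping** (`destripe_slice()`, `destripe_volume()`).  Stripe shadows
are multiplicative attenuation lines that are (nearly) constant along one
image axis — here along slice dim 1 (y), i.e. each column x carries a
common factor.  A multi-level 2D Daubechies-3 wavelet decomposition
(periodized; implemented in the package and verified by perfect
reconstruction tests) isolates stripe energy in the bands that are
high-pass across the stripes and low-pass along them.  Those bands are
Fourier transformed along the stripe axis, where stripe content
concentrates at frequency zero, and multiplied by the notch
`g(k) = 1 - exp(-k^2 / (2 sigma^2))` (`k` in cycles per slice extent).

* `sigma` (default **1 cycle**): pure stripes sit exactly at `k = 0`
  where the gain is 0 for any sigma, so the default is chosen narrow to
  spare legitimate structure; widen it for wavy stripes.
* `levels` (default `min(5, floor(log2(min(dim))))`, stopped early when a
  band would drop below the filter length + 2): depth matters because the
  stripe's across-axis frequency only reaches the high-pass bands after
  enough dyadic splits.

An inherent limitation: image content that *is* stripe-like — smooth
along the stripe axis, varying across it — is attenuated with the
stripes; no notch filter can distinguish them.

**Debleaching** (`debleach()`) is flat-field correction: divide by a 3D
Gaussian low-pass estimate of the smooth brightness field (divisor
floored at `1e-3` of its maximum), then rescale to preserve the mean.
The default `lowpass_sigma` is 1/8 of the smaller lateral extent: large
enough not to track individual cells, small enough to follow the bleach
field.  Near volume borders the mirror-padded low-pass cannot follow a
non-zero field slope, so a thin boundary band retains a few percent of
residual non-uniformity.

**Deconvolution** (`deconvolve()`).  Lightsheet optics blur a point into
an axially elongated ellipsoid; the default PSF model is a separable
Gaussian with `sigma_z = 2.5 * sigma_xy`, reflecting the roughly 2.5-fold
axial smear of this imaging mode.  Restoration uses Richardson–Lucy
multiplicative updates (default **10 iterations**, mirror boundaries):
non-negative by construction and flux-conserving for interior signal.
RL was chosen over Wiener-style inverse filtering because thresholding
downstream depends on non-negative, ringing-free output.

**Conversion.**  `select_threshold()` picks the intensity whose
strictly-above fraction is closest to `fg_percent` (ties toward fewer
foreground voxels).  For corrupted phantoms the pipeline convention is to
request **2x the clean foreground fraction**: ranking by brightness at
the exact labeled fraction loses the dim halves of blurred thin branches,
while the extra noise voxels admitted at 2x are discarded later as
unreachable.  On real data, 0.8% is a good starting point for sparsely
labeled brains.

## Seed (soma) detection

The label binds only to the cell surface, so somas appear as spherical
shells.  `segment_seeds()` works on the *surface* of the foreground mask:
closing with a ball of `close_radius` voxels fills the shell cavity,
opening with `open_radius` erases branches, and 26-connected components
become instances with a µm centroid and an equivalent-sphere radius.

Defaults are tied to the phantom geometry (somas 5–7 µm radius with
2-voxel shells, branches up to 2 µm radius at 1 µm sampling):

* `close_radius = 5` — must reach the shell cavity radius
  (soma radius − shell thickness);
* `open_radius = 4` — must erase not only single branches but also
  bundles that the closing step fuses (two 2 µm branches side by side);
  radius 3 leaves marginal bundle fragments that masquerade as small
  somas;
* `min_voxels` — the voxel count of a ball of radius `open_radius`;
  anything smaller survived the opening only as an artifact.  Set
  `min_voxels = 0` to reproduce unfiltered high-recall seed output.

Morphology itself is exact Euclidean-ball Minkowski algebra on the
sparse mask.  Erosion treats out-of-domain voxels as background; closing
is evaluated on a radius-padded grid so that it remains extensive
(`m` is always contained in `close(m)`) even at volume borders.

## Cell segmentation by seeded fast sweeping

`fastsweep()` solves the eikonal equation `|grad u| = 1` restricted to
mask voxels with `u = 0` on the seed surfaces: `u` is geodesic arrival
distance (µm) through the foreground.  Updates are first-order upwind
with per-axis physical spacing, applied in the 8 axis-ordering
Gauss–Seidel sweeps until the largest change drops below `tolerance`
(default `1e-3` µm).  The local update additionally folds in a
26-neighbor graph relaxation; a pure 6-stencil update cannot propagate
along single-voxel-wide diagonal runs, whereas the hybrid keeps every
26-connected voxel reachable and never exceeds the 26-neighbor Dijkstra
distance.  At convergence the field equals its order-independent fixed
point, so sweep order is immaterial to the result.

Two details worth knowing:

* Arrival values measure distance to the implicit *front* through the
  seed voxels.  With extended (multi-voxel) sources a value can be less
  than the distance to the nearest individual seed voxel — e.g.
  `1/sqrt(2)` µm for a voxel diagonally between two adjacent sources.
* Unreached voxels are simply absent from the field; `prune_unreached()`
  is a linear scan that keeps exactly the reached set, and
  `split_cells()` cuts it into 26-connected instances annotated with the
  seeds they contain (two or more seeds flag a cluster).

`close_branches()` optionally closes the mask before sweeping.  This is
the pipeline's main break-versus-collision dial: radius 1 (the default)
bridges single-voxel breaks; larger radii bridge larger breaks but begin
to fuse neurons whose branches pass within a few µm of each other — in
the phantom cohort a radius of 4 fused two neurons whose tube surfaces
came within ~2 µm, which is far more damaging to topology scores than
the breaks it repairs.  Raise the radius only for heavily broken masks.

## Skeletonization by local separators

Each cell instance's surface voxels form a graph (vertices at voxel
centers, edges between 26-adjacent surface voxels).  The stages:

1. **Coarsening** (`coarsen()`, default **2 steps**, 4 for sub-µm
   voxels): light-edge matching — a maximal matching preferring the
   shortest edges, contracting matched pairs to weighted midpoints.
   Contraction cannot create or merge components (asserted per step).
   Coarsening erodes high-curvature termini slightly, which is the main
   reason distal leaf recall is the weakest score.
2. **Local separators** (`find_separators()`): from each not-yet-covered
   vertex in deterministic order, a ball grows in breadth-first rings
   until its front splits into two or more components; the ball is then
   greedily minimized while its neighbor set still splits.  Minimized
   separators are thin rings around branch "waists".  Found separators
   are packed greedily (vertex-disjoint, discovery order);
   `pack_separators()` offers the cardinality-ascending variant.
   On closed surfaces (an isolated soma sphere) no front ever splits;
   such components contribute one whole-component node.  The growth cap
   `max_ball` (default 4000 vertices) bounds per-seed work.
3. **Quotient skeleton** (`build_trees()`): separators become nodes
   (weighted centroid, mean vertex-to-centroid radius).  Regions of
   uncovered vertices touching exactly two separators act as edges;
   regions touching one (terminal caps) or three or more (junction hubs)
   become nodes as well — this preserves leaf tips and guarantees a
   proper branch node at junctions.  Each tree is rooted at a type-1
   node at the seed centroid (the field convention for SWC somas);
   quotient nodes inside the soma radius are absorbed into the root,
   since the soma surface is one body rather than a chain of waists.
   Remaining nodes join the seed that reaches them first along a
   multi-source metric shortest-path forest; hop-count BFS was rejected
   because junction shortcut edges could re-root whole arms.
4. **Standardization** (`standardize()`): ids re-indexed 1..N
   parent-before-child, coincident nodes merged (max radius), zero-length
   segments collapsed, radii floored at half the smallest voxel
   dimension, exactly one root.  The operation is idempotent and every
   emitted SWC satisfies it.

## TreeBench: topological accuracy

`match_nodes()` implements three-step matching of gold to test nodes:
(1) candidates within `dist_threshold` (default **8 µm**, the diameter of
the largest branch points in typical gold sets); (2) some already-matched
gold ancestor must have its match on the candidate's ancestor path —
climbing beyond the nearest matched ancestor is allowed, which stops a
single greedy mis-capture just after a junction from cascading down the
arm; (3) the path lengths from node to that ancestor must agree within
`path_tolerance` (default **0.2**, relative to the gold path length with
the distance threshold as a floor on the denominator).  Matching is
greedy by Euclidean distance, root-first, one-to-one.

`diadem_score()` aggregates over gold *critical* nodes — branch nodes
and terminals, excluding the root — weighted by the number of terminals
in each node's subtree.  An identical pair scores exactly 1.
`decomposed_scores()` reports recall / branch / leaf / direction /
precision around the same matching (`direction` compares parent-pointing
unit vectors of matched branch nodes by sign of the dot product; empty
categories are `NA`, never `NaN`).  `cohort_yield()` is the fraction of
reconstructions within 2 sample standard deviations of the cohort mean
topology score.  `score_seeds()` scores detections against gold somas
with the one-radius tolerance, greedily and one-to-one.

Because the skeletonizer emits nodes at separator spacing rather than at
the gold node spacing, precision is structurally below 1 even for a
perfect trace (extra nodes between gold samples are unmatched by the
one-to-one rule); topology, recall, branch and direction are the
informative columns for reconstruction quality.

## The phantom generator

`phantom_spec()` fixes the study conditions; `generate_phantom()` is
fully reproducible from its seed.  Defaults: a 256^3 volume at 1 µm
isotropic sampling with 3 neurons; somas of radius 5–7 µm drawn as
shells of 2-voxel thickness (surface-only labeling, dark interiors);
two primary neurites per cell emerging at the soma surface; recursive
branching to depth 3 with probability 0.6 and segments of 25–45 µm
sampled every 4 µm; tube radii 1–2 µm, non-increasing downstream.
Corruption applies, in order: multiplicative sinusoidal stripes along x
(amplitude 0.3, period 37 voxels — deliberately incommensurate with
dyadic wavelet scales), a smooth multiplicative bleach field (linear
ramp times a broad Gaussian, dimming to 0.3), the anisotropic PSF
(`sigma_xy` 1 µm, `sigma_z` 2.5 µm), additive Gaussian noise (sd 4 on
the 8-bit scale) and optional Poisson resampling, then clamping.

What the phantoms *do not* emulate: autofluorescent background tissue
and vasculature, tile seams and stitching errors, depth-dependent PSF
variation, intensity heterogeneity along a single branch, and the sheer
density of real whole-brain data where hundreds of cells and their
clusters interact.  Passing the phantom suite shows the algorithms are
implemented correctly under controlled conditions; it does not certify
accuracy figures on real brains.  Neuron placement does not enforce
clearance, so close passes and genuine collisions do occur and are part
of the tested conditions.

## Problem sizes and determinism

The shipped test-suite runs use desk-scale sizes chosen so the full
suite exercises every stage end to end: canonical shapes at ~24^3–80,
oracle comparisons at 16^3–24^3, noiseless pipeline runs at 96^3, seed
cohorts at 128^3, and five full corrupted-pipeline replicates at 256^3
with 3 neurons each.  A 256^3 end-to-end run (phantom generation through
benchmarking) takes on the order of 1–2 minutes on one CPU core.

Every run is a deterministic function of (input volume, configuration):
the pipeline itself draws no random numbers, C++ kernels are
sequentially deterministic, and SWC output uses shortest round-trip
decimal formatting, so repeated runs are byte-identical.  Stage
manifests record parameter fingerprints and input hashes; `resume`
reuses artifacts only when both match.

## Known limitations

* Distal termini are systematically shortened by surface coarsening;
  leaf recall is the weakest decomposed score, as expected for this
  family of methods.
* The separator quotient assumes tubular geometry; flat sheets or highly
  non-tubular shapes would produce few separators and coarse skeletons.
* Seed detection distinguishes somas only by size and shape after
  closing/opening; dense debris fields of soma scale would produce false
  positives (a learned second-pass filter is out of scope).
* Anisotropic voxels are handled in the sweep metric and in µm
  positions, but morphology uses isotropic voxel balls; strongly
  anisotropic data should be z-downsampled first (`z_factor`).
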