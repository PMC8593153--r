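---
title: "Quantifying root architecture and soil kinematics from time-series micro-CT"
author: "rhizoCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying root architecture and soil kinematics from time-series micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A plant root growing through sand is both a biological and a mechanical
event: the root invades existing pores and displaces grains, shearing and
dilating (or compacting) the soil around it. Daily X-ray micro-CT of a
root–sand specimen yields a chronosequence of 3D greyscale volumes from
which three families of quantities can be measured:

* **root-system architecture** — branch hierarchy, lengths, tip depth,
  cross-section sizes, root length density (RLD, m of root per m³ of
  soil);
* **rhizosphere porosity** — the pore fraction (air + water over total
  soil) as a function of depth and of distance from the root surface, and
  its day-to-day change Δn;
* **soil kinematics** — displacement fields between Day 0 and later days
  (window digital image correlation, DIC, for fine sand; grain tracking
  for coarse sand), the per-point transformation gradient **F**, and its
  invariants: volumetric strain ε~v~ = det(**F**) − 1 (dilation positive)
  and deviatoric strain ε~q~, the Euclidean (Frobenius) norm of the
  traceless part of sym(**F**) − **I**.

`rhizoCT` implements this full chain, plus a synthetic scene generator
that builds CT-like volumes with complete ground truth (phase labels,
grain centres, exact skeleton, analytic displacement fields) so every
stage can be validated quantitatively without any scan data.

# Pre-processing

Grey levels must be comparable across days before thresholds calibrated
on Day 0 can be reused. `findHistogramPeaks()` locates the most prominent
modes of the grey histogram (Gaussian-smoothed, default sd 3 grey levels;
peaks ranked by topographic prominence), and `contrastStretch()` applies
the affine map through the lowest and highest peak onto the reference
day's peaks — a two-anchor linear stretch. `downscale()` bins the volume
by an integer factor with block means (factor 2 by default: 40 µm
acquisition voxels become the 80 µm working pixel, the voxel count drops
by 8, and the averaging already denoises). `denoiseBilateral()` then
applies an edge-preserving 3D bilateral filter.

Two numerical choices matter here:

* the bilateral **range sigma** defaults to 3× a robust noise estimate
  (the low decile of tiny-window variances, which sits in homogeneous
  regions even when most of the image is granular texture), capped at
  half the minimum inter-peak distance. A range sigma tied only to the
  peak spacing over-smooths the water/sand contrast and welds sand and
  pendular water into artificial homogeneous blobs that later confuse the
  root segmentation;
* block **means** (not decimation) are used for downscaling, so the grey
  sum is conserved exactly when dimensions divide the factor (the image
  is cropped, with a message, when they do not).

# Four-phase segmentation

Each voxel is assigned to exactly one of air (0), water (1), sand (2) or
root (3).

**Sand** is the densest, brightest phase. Its grey threshold is not
chosen by eye: `calibrateThresholdByVolume()` picks the threshold whose
segmented volume matches the physical solid volume computed from the dry
sand mass and the grain density (default 2.65 g/cm³ for silica). The
segmented-volume-versus-threshold curve is monotone, so the optimum is
read off the sorted grey values directly. **Water** is calibrated the
same way against the poured water volume on Day 0; both thresholds are
then reused unchanged on later days.

**Root** tissue has nearly the same attenuation as pore water, so
thresholding cannot isolate it. `segmentRoot()` uses a 3D variance
filter: every voxel is replaced by the population variance of the greys
in the cubic window of half-width r~v~ centred on it (`varianceFilter()`,
windows clipped at the image edge). Homogeneous interiors — the air above
the sand surface, the root body, large pores — score low; the granular
matrix, full of grain/pore interfaces, scores high. Low-variance voxels
are labelled by 26-connectivity, components are ranked by volume, the
largest is the image background (air headspace; a `background = FALSE`
flag makes the largest the root when no headspace is imaged), the second
largest is the root body, and the rest are connected pores. Exact volume
ties are broken towards the lower mean variance (the more homogeneous
component). The variance filter erodes the root edge, which is recovered
by dilating the root component n = ⌊r~v~/2⌋ times (minimum 1), never
overwriting sand.

Design choices the package had to make where the procedure is
under-determined:

* **automatic variance threshold**: 0.45× the median variance of the
  sand matrix (the sand mask is available, having been segmented first).
  This sits between the homogeneous interiors (near zero) and the granular
  texture, and is exactly scale-equivariant under affine grey maps —
  variance scales with the square of the gain, and so does the matrix
  median. Otsu on the square-root variance map is the fallback when no
  sand mask is supplied.
* **dilation element**: an isotropic Euclidean ball realised through the
  exact distance transform, rather than an iterated cubic (26-connected)
  element that over-grows diagonals.
* **grey verification**: the dilated mask is compared back to the
  greyscale image; voxels with air-like greys (below an Otsu split of the
  non-sand greys) are returned to the pore class, a small
  grey-constrained closing regrows the sub-voxel shell blurred by the
  point spread, and only the part of the mask connected to the
  variance-filter core is kept. Without this, air pockets touching the
  root inflate the mask.
* **resolution flag**: a recovered root whose maximum cross-section
  (2× the distance-transform radius) is below 4 voxels is flagged as
  sub-resolution (`detectable = FALSE`); at the 80 µm working pixel this
  reproduces the 320 µm minimum detectable cross-section.

**Grains** in coarse sand span tens of voxels and can be individualised:
`labelGrainsWatershed()` floods the negated Euclidean distance transform
from markers at its regional maxima (smoothed, plateau-merged), and
merges labels below a minimum volume into their dominant neighbour.

`assembleFourPhase()` resolves any mask overlap with the precedence
sand > root > water > air and verifies that every voxel is labelled.

# Root architecture

`skeletonGraph()` thins the root mask to a one-voxel centreline by
directional border peeling: a voxel is deleted only if it is *simple*
(its removal provably preserves both object and background topology in
its 3×3×3 neighbourhood) and not an endpoint. Because thinning retreats
about one radius from tube tips, every endpoint is extended along its
local direction to the mask boundary. The centreline becomes a spatial
graph (26-adjacency); spurs shorter than 3× the local radius are pruned.
The local radius at every node is the Euclidean distance to the
background minus half a voxel (the surface-sampling bias); the root
cross-section size at a node is twice that. On analytic cylinders of
radius 3–10 px the radius bias stays below half a pixel.

Branch lengths are sums of inter-node Euclidean steps after a light
moving-average smoothing of the path coordinates (window 5, ends
anchored), which removes the staircase overestimation of digital
centrelines; on a straight 100-voxel cylinder the measured length is
within 2 %.

`labelHierarchy()` roots the graph at the node nearest the seed and
decomposes it as a tree of axes: the **primary** (order 1) is the
deepest-reaching path (ties within 1 % of depth go to the longer path,
with a warning); each subtree hanging off an order-k axis becomes one
order-(k+1) branch whose own axis is the farthest path from its
attachment node. Subtrees shorter than about two of their own local
diameters are absorbed as thinning artefacts — artefact wiring lives
*inside* the parent tube and therefore carries the parent's thick radius,
while a real lateral is its own thin tube, which is what makes the
cutoff discriminative. Junction nodes belong to the parent branch.

`architectureMetrics()` reports RLD (total branch length over soil
volume), tip depth below the sand surface, lateral count (order ≥ 2),
primary length and the day-to-day elongation rate. For an unbranched
synthetic root the recovered RLD is within 3 % of the ground-truth length
of the imaged root phase; for branched roots, junction geometry and
tapered lateral tips near the resolution limit cost up to ~15 %, which is
why lateral lengths should be read as lower bounds at this voxel size.

# Porosity

Porosity is pore voxels (air + water) over soil voxels; the root body is
not soil and is excluded from numerator and denominator.
`verticalPorosityProfile()` bins by depth slabs, excluding everything at
and above the seed (the seed disturbs the pluviated packing).
`shellPorosityProfile()` bins soil voxels into concentric iso-distance
shells of the Euclidean distance transform of the root surface — a
"hollow volume" coaxial with the root axis that generalises to curved
axes — with shell thickness D50/2 by convention (169 µm for D50 = 338 µm;
the analysis also accepts the rounded 160 µm). With a branch selector,
root voxels are first assigned to branch territories by nearest skeleton
node, and only voxels whose nearest root voxel belongs to the selected
branch are counted. Shells with fewer than 100 voxels are flagged as low
support. `deltaPorosityProfile()` subtracts the Day-0 profile and
locates the **dilated-zone extent**: the distance up to which porosity
stays above the initial bulk value, taken at the *first* crossing because
the dilated zone is contiguous from the root surface. Note that when the
far field sits exactly at the bulk porosity the first crossing is a
noisy estimator; it is crisp whenever the far field is even slightly
compacted, which is the configuration of interest.
`degreeOfSaturationMap()` computes the moving-window proportion of pore
space occupied by water via separable box sums; windows without pore
voxels are undefined.

# Kinematics

`localDIC()` divides the volume into a structured grid of cubic
correlation windows (default side 1.3 mm, non-overlapping by default) and
finds, per window, the integer-voxel translation maximising the
normalised cross-correlation, then refines it to sub-voxel precision by
iterative trilinear-interpolated least squares with a grey-offset term.
Windows are translation-only — the window side is far below the strain
length scale. Three practical safeguards: a grey-variance floor flags
featureless windows, a correlation floor (0.6) flags poor matches, and
both volumes are pre-smoothed with a σ = 1 voxel Gaussian, without which
the sub-voxel iteration stalls on the kinked residual landscape that
trilinear interpolation produces on sharp granular texture. On textured
synthetic scenes, integer shifts are recovered exactly and half-voxel
shifts to ~0.02 voxel mean error (the acceptance bound is 0.1).

`trackParticles()` matches labelled grains between days by nearest
centre of mass within a search radius, gated on the grain-volume ratio
(0.8–1.25), with conflicts resolved by greedy global assignment on
distance; unmatched grains are flagged.

`strainGeers()` fits, at every converged point, the displacement
gradient by uniform-weight least squares of relative displacements
against relative positions over the surrounding neighbourhood (default
radius 1.75× the grid spacing — the 26 grid neighbours); **F** = **I** +
∂u/∂X. Points with fewer than 4 usable neighbours or a near-coplanar
neighbourhood are masked, not errors. `strainBagi()` is the discrete
route: a Delaunay tetrahedralisation of the measurement points (an
incremental insertion algorithm; a deterministic 10⁻⁶-relative jitter
breaks cospherical grid ties, while strain is always computed from the
true coordinates) and the uniform per-tetrahedron gradient of the linear
displacement interpolant. Both routes are exact on affine fields to
10⁻¹⁰ and agree there; a 1° rigid rotation leaves |ε~v~| below 2×10⁻⁴
(second order).

`strainInvariants()` uses ε~v~ = det(**F**) − 1. The phrase "determinant
of the transformation gradient (**F** − **I**)" admits two readings;
det(**F** − **I**) is cubically small for percent-level strains and
cannot produce percent-scale volumetric strains, so the determinant
identity on **F** is the only self-consistent choice. ε~q~ is the plain
Frobenius norm of the deviatoric small-strain tensor by default; the
√(2/3) von Mises scaling is selectable. The **engaged volume** is where
ε~q~ exceeds 1 % (a noise floor for shear-strain measurements);
`strainClouds()` splits engaged points into an immediate vicinity
(within 1–1.5 window widths of a root-containing window) and a further
neighbourhood (to 5 windows), excluding points inside root windows, and
reports the ε~v~ centroid per ε~q~ bin — the summary in which loose sand
shows near-root dilation with far-field compaction.

# The synthetic scene generator

The generator's defaults are the study conditions: fine sand with
D50 = 338 µm and porosity bounds 0.39–0.51 (loose state D~R~ = 28 % ⇒
n ≈ 0.475; dense D~R~ = 79 % ⇒ n ≈ 0.43), 80 µm voxels, a primary root of
300 µm radius (0.6 mm cross-section, 7.5 px) with three laterals at 0.7×
that radius, partial saturation as pendular water, per-phase grey means
(air 30 ≪ water 105 ≈ root 115 ≪ sand 190), a Gaussian PSF of 0.4 voxel
(the residual blur of a downscaled acquisition that still resolves
4-voxel grains) and Gaussian noise of 5 grey levels. Scenes are
bit-reproducible from their configuration seed.

**Packing.** Mechanical pluviation is deliberately not simulated.
Spheres with lognormal radii (median D50/2, CV 0.2) sit on a jittered
face-centred-cubic lattice (spacing 1.05 D50, 2 % jitter); overlaps are
resolved by a damped fixed point of r~i~ = min(cap, min~j~(d~ij~ − r~j~))
followed by a strict pairwise enforcement pass, and the target porosity
is met (±0.01, verified on the voxelised pack) by deleting grains with a
blue-noise spacing so that looseness is homogeneous rather than
concentrated in multi-grain cavities. Unreachable targets fail with the
achievable range. Two consequences to keep in mind: the effective size
spread narrows at high density (output CV ≈ 0.1 for requested 0.2 — the
price of non-overlap on a lattice), and the pack retains weak lattice
layering that real pluviated sand does not have.

**Root and seed.** The primary axis random-walks downward with
configurable tortuosity and a linear taper; laterals emerge at 50–70°
from vertical, run straighter than the primary, and are re-drawn (new
azimuth) until they stay clear of the primary and of each other —
crossing tubes would merge into one mask component that no skeleton
could separate, which is also true of real roots. The root displaces
grains: grains swallowed by the tube are removed, grains straddling its
surface are shrunk until they sit against it (recorded in the grain
table), so no artificial air annulus surrounds the root, but a genuine
steric-exclusion porosity rise remains in the first grain layer — as in
real rhizospheres. A dense ellipsoidal seed kernel is rendered at the
seed position; it blocks any air path between root and headspace (whose
absence would make background and root one component) and absorbs the
root tissue inside it, which CT cannot resolve either.

**Water.** Geometric, not capillary-mechanical: full saturation below a
configurable water table plus pendular bridges — the one-voxel pore shell
hugging grain surfaces inside narrow throats (local solid fraction
≥ 0.62) — within the capillary band. The default scene carries only
films (table at the bottom), reflecting a watered-from-below fine-sand
specimen in which pore water is distributed, not ponded; a bulk saturated
zone is available via `waterTableDepth` but note that a large connected
water body is itself a low-variance component that can outrank the root
in the variance-filter ranking — a genuine failure mode of the method,
not of the implementation.

**Warping.** `warpScene()` imposes a rigid translation, an affine map,
or a radial field u~r~ = a·exp(−r/λ) about the root axis by inverse
mapping with trilinear interpolation, returning closed-form displacement
and gradient evaluators as DIC/strain ground truth. Inverse maps are
exact for translations and affine maps and fixed-point iterated for the
radial field; material entering from outside the image is filled with
background grey and flagged. Warping by **F** then **F**⁻¹ restores a
smooth volume to better than 2 grey RMS; on voxel-sharp texture the
double interpolation irreversibly removes high frequencies, so that
round-trip property is only meaningful for band-limited content.

**What passing on these scenes does not show.** Spherical grains cannot
reproduce angular-grain interlocking; the imaging model has no beam
hardening or ring artefacts; the water model has no menisci physics; and
contrast/noise are idealised. Results on synthetic scenes validate the
*machinery* — calibration logic, topology, oracles, error bounds — not
scanner-specific performance. In the same spirit, the variance radius
that best resolves a 7.5 px root at the synthetic contrast is r~v~ = 2;
the r~v~ = 4 working value for fine sand belongs to the original imaging
conditions, and both are plain parameters here.

# Problem sizes and budgets

The shipped tests and the acceptance script run entirely on generated
data at desk scale: default scenes are 80×80×120 voxels (6.4×6.4×9.6 mm
at 80 µm) with ~10⁴ grains, the kinematics experiment uses 113×113×120,
and coarse-sand demonstrations use 120–160³ voxels at 120 µm. A scene
generates in ~10 s and the full chain on one scene runs in ~15 s on one
CPU; the complete test suite is a few hundred assertions in ~7 minutes.

# Known limitations

* Skeleton length changes by up to ~2.5 % under 90° volume rotations
  (the thinning's directional sub-iterations are axis-ordered), slightly
  above the ±2 % one might hope for.
* Branched-root total length is recovered to ~15 % (junction territory
  and tapered tips), against 1–3 % for unbranched axes.
* The segmented root body is systematically ~10 % thinner than truth
  (grey verification trims the blurred shell), so cross-section sizes
  read low by roughly one PSF width.
* The discrete (Bagi) route uses floating-point incremental Delaunay;
  for degenerate inputs beyond the deterministic jitter's reach it can
  drop slivers rather than repair them (they are flagged).
* Day-to-day volumes are assumed rigidly aligned (fixed cell), as in the
  acquisition protocol; no registration is performed.
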