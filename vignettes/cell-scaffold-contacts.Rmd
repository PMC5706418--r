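---
title: "Measuring cell-scaffold contacts from dual-channel confocal z-stacks"
author: "cellscaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cell-scaffold contacts from dual-channel confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellscaffold)
```

## The measurement problem

A cell cultured on a biomaterial scaffold is imaged by confocal laser
scanning microscopy in two co-registered channels: one excites the cell
membrane stain, the other the scaffold stain. The quantity of interest is
the set of voxels where the cell touches the scaffold — the 3D contact
sites — because the geometry of those contacts (one plane on a flat film,
several planes on a fiber mesh) is what a scaffold designer can control.
Contact here is *object-based*: cell and scaffold labels co-occurring at a
voxel or lying within one voxel of each other, rather than an intensity
correlation. This choice keeps the result a shape, which is what downstream
morphometry needs.

Two facts shape the design. First, the raw data are enormous (a single
field of view is a pair of 2048 x 2048 x 100+ 16-bit stacks), so every
stage must operate on cropped regions of interest around a verified cell
segmentation. Second, the two fluorophores' emission spectra overlap, so a
bright cell leaks into the scaffold channel (bleed-through); any scaffold
model that trusts raw intensities will hallucinate scaffold inside the
cell.

## Statistical and geometrical scaffold models

The package implements two families of scaffold segmentation, because they
embody different amounts of prior knowledge.

The *statistical* models A1-A5 make assumptions only about intensities.
All are per-voxel foreground probabilities against a background model
(mean and SD of the first or last z-frame, which lies outside the
specimen). The published study names the five models but the concrete
per-model definitions live in supplementary algorithm documents; the
instantiations here are this package's own, chosen to be the simplest
rules faithful to each model's name:

- **A1 (single-pixel)** is the Gaussian upper-tail posterior
  `pnorm((I - mu)/sigma)`. In the zero-spread limit only strictly brighter
  voxels count as foreground.
- **A2 (mixed-pixel spatial)** treats a voxel as a background/foreground
  mixture and returns the mixture fraction, with the foreground reference
  intensity taken as the 99th percentile of A1-positive voxels, pooled
  over an in-plane 3 x 3 window (the axial point-spread function already
  mixes along z).
- **A3 (mixed-pixel channel)** first estimates the bleed-through
  coefficient and subtracts the leaked partner signal, then applies A2.
  The coefficient is the median of `(I - mu)/(I_partner - mu_partner)`
  over strongly partner-positive voxels: on pure-partner voxels this ratio
  *is* the mixing coefficient, and the median ignores the minority of
  voxels where both structures genuinely overlap (a least-squares fit over
  the same voxels is biased upward by exactly those overlaps, which is why
  the robust form is used).
- **A4 (additive noise)** fits a two-component Gaussian mixture by EM with
  the background component pinned to the background model and returns the
  foreground responsibility.
- **A5 (MRF)** regularizes the A1 posterior with an Ising prior
  (6-neighborhood, smoothing weight beta = 1, at most 10 iterated-
  conditional-modes sweeps) and returns the smoothed soft posterior.

The *geometrical* models commit to a shape: spun-coat films are planes,
electrospun fibers are tubes. For films, the upper and lower surface
voxels (per-column extremes of the thresholded stack, weighted by
background-subtracted intensity) are fitted by weighted total least
squares; the residual standard deviation

$$\mathrm{STD}^{RES}_k = \sqrt{\frac{\sum_i w_{ki}\, f_k(x_i,y_i,z_i)^2}
{\sum_i w_{ki} - \bar{w}_k\, p}}, \qquad p = 3$$

and its pooled form across stacks quantify how planar the film really is;
on the real material this lands near 100 nm, below a single voxel, which
is what justifies the planar model in the first place. For fibers, a
Frangi vesselness filter (Hessian eigenvalues at scale sigma = 1.0 for A6,
1.5 for A7, standard constants alpha = beta = 0.5, structureness constant
half the maximum Hessian norm) enhances tubes, and the maximum-entropy
threshold binarizes the response. A8 is the deliberately naive baseline:
threshold, median filter, drop components under 27 voxels.

Both routes binarize with the same maximum-entropy (Kapur) criterion: the
threshold maximizes the sum of Shannon entropies of the renormalized
below- and above-threshold histogram halves (256 bins over the data range;
ties resolve to the lowest cut, and the threshold value is the lower edge
of the first foreground bin so that `volume >= threshold` reproduces the
split exactly).

## From probabilities to contacts

The statistical route combines the two channels by the law of total
probability: `P(Contact) = P(Contact|Cell) P(Cell) +
P(Contact|Scaffold) P(Scaffold)`. The class priors come from K-means
(K = 3) on the 2D scatter of (cell, scaffold) intensities; each voxel's
distances to the background, cell and scaffold centroids are converted to
probabilities by inverse-distance weighting, which satisfies the sum-to-one
constraint and the exact-hit limit (a voxel on a centroid gets probability
one). The centroid nearest the origin is background; of the other two, the
one with the larger cell-channel coordinate is the cell. K-means is seeded
deterministically from the run seed and re-seeded up to five times if a
cluster empties. Contact *sets* for both routes use the object-based
definition (`binary_contact()`, 26-neighborhood by default, configurable
to 6 or 18); contact *surfaces* are the segment voxels with nonzero
central-difference gradient, with volume-border voxels excluded so crop
boundaries never register as surface.

Competing probability maps are compared by the RMS distance
`sqrt(sum (p_i - p_j)^2 / XYZ)`, an L2 metric on [0, 1]. On the bundled
fixtures the A2-A3 pair is the closest of all model pairs — the mixed-pixel
channel model collapses to the spatial one when bleed-through is small —
which is the desk-scale echo of the published down-selection of A2.

## Single-fiber validation

Fiber segmentation accuracy is validated on single-fiber scenes by
comparing radii. The segmented fiber is reduced to a centerline, each
centerline point is assigned a radius, and the radius histogram is
compared against an orthogonal reference (in the original study,
electron-microscopy measurements of the same fibers; here, phantom ground
truth plus the bundled published summary table).

Skeletonization deserves its numerical notes. Topology-preserving
simple-point thinning with only a curve-endpoint stopping rule is unstable
on ideally rasterized cylinders: when the medial axis falls between
voxels, a deletion front can sweep through a two-voxel-thick plate and the
solid collapses (the widely used reference implementation of medial-axis
thinning exhibits exactly this on even-width rods). The package therefore
(1) anchors the ridge of the chamfer (3-4-5) distance transform — those
voxels are never deleted, (2) thins everything else by sequential
simple-point deletion, (3) runs a final endpoint-protected pass over the
eight voxel-parity subfields (within a subfield no two voxels are
26-adjacent, so deletions cannot cascade) to reduce two-voxel ties to a
single-voxel curve, and (4) prunes residual spurs by iterative endpoint
removal to a depth of the object's inradius plus two voxels. The result on
a straight cylinder is a centerline within one voxel of the true axis with
exactly two endpoints.

The per-point radius comes from casting 16 rays at equal angles in the
plane normal to the local tangent (tangents are central differences of
points two steps apart along the traced branch, in physical coordinates so
anisotropic voxels are handled), recording the boundary crossing of each
ray, and taking `sqrt(2 * lambda_min)` of the *population* covariance of
the in-plane boundary coordinates. The `sqrt(2 .)` calibration is fixed by
the closed form for a uniform circle (both in-plane eigenvalues equal
r^2/2) and makes the covariance-eigenvalue mechanism dimensionally a
length; with the sample (n-1) covariance the estimator would be biased by
n/(n-1) in variance. Points within three steps of a branch end or junction
are excluded — the medial radius is ill-defined there. On rasterized
cylinders of radius >= 4 voxels across ten random orientations the mean
radius lands within 10% of truth (typically within 4%).

The "ALL versus Internal" subsets of the published workflow (all fields of
view versus their non-overlapping cores) are represented at desk scale by
restricting skeleton points to a central sub-box; multi-field stitching
itself is out of scope.

## The phantom generator

`phantom_spec()` / `render_phantom()` emulate the acquisition: geometry is
rasterized by the voxel-center-inside rule (no antialiasing, so analytic
volume and mask oracles are exact), then blurred by a separable Gaussian
point-spread approximation specified in micrometers (default
0.6 x 0.2 x 0.2 um, matching the instrument class's axial/lateral
resolution ratio), mixed across channels by a single symmetric linear
bleed coefficient, offset, and degraded with i.i.d. Gaussian noise. The
defaults — background offset 150, noise SD 30, bleed 0.05, cell intensity
around 1400 and scaffold around 900 on the 16-bit scale — give the
bright-cell/dimmer-scaffold contrast and comfortable signal-to-noise of a
well-acquired stack; the published study demonstrates bleed-through but
does not quantify it, so 0.05 as a routine level and 0.3 as the stress
case are this package's choices. Linear symmetric mixing is the minimal
model of spectral overlap; the generator does not attempt a physical
optics simulation, spectra-based emission models, or depth-dependent
aberrations, so passing tests certify algorithmic correctness on ideal-PSF
data, not robustness to every real-microscope artifact.

Fixture geometry follows the study's materials: fibers of radius 1.3 um
(large microfiber) and 0.55 um (medium), a flat slab for spun coat, and
ellipsoidal cells a few micrometers across draped on them. Most fixtures
use isotropic 0.25 um voxels to keep volumes small; the end-to-end
contact-recovery scene uses the instrument's anisotropic sampling
(0.462 x 0.12 x 0.12 um), where the blur-to-voxel ratio matches the real
acquisition.

## Preprocessing choices

The region of interest is the cell bounding box expanded by 10% of its
width/height per x/y side. The z bounds come from the scaffold channel's
z-profile: the per-z maximum of the [X, Z] maximum projection, smoothed by
a Gaussian kernel of length 21 with SD 5 frames (reflected boundaries);
the crop bounds are the zero-crossings of the smoothed profile's second
derivative (central differences) nearest below and above the profile
maximum. "Inflection points in the second derivative" is read as the
frames where the curvature changes sign — the reading consistent with
marking the shoulders of the intensity bump; a missing crossing on one
side falls back to the volume edge with a warning, stacks under 25 frames
are returned uncropped, and the procedure is invariant to constant
intensity offsets because the second difference annihilates them.

Cell segmentation is intentionally a simplified stand-in (the full
permutation-optimized membrane segmentation of the original workflow is
its own algorithm): maximum-entropy threshold, largest 26-connected
component, per-slice hole filling, one binary closing. A plausibility
guard converts pure-noise stacks to a `"missed"` status instead of
returning the clipped noise tail: the foreground's median intensity must
exceed the stack median by at least four robust SDs. On a noiseless
ellipsoid the mask is exact; at signal-to-noise 5 the Jaccard index
against truth exceeds 0.9.

## Verification statistics

Expert labels (cells: good/correct/incorrect/missed; contacts:
excellent/acceptable/bad) are summarized by two figures. *Accuracy* is the
fraction of items that at least one expert rated positive under the
combined grouping ({good, correct} and {excellent, acceptable} versus the
rest). *Precision* is the mean over expert pairs of the fraction of shared
items with matching grouped labels; given already-published pairwise
ratios, their mean is the same statistic. The bundled reference tables
carry the published per-spot AFM roughness values, verification counts,
pairwise agreement ratios, per-type bad-contact counts and the
single-fiber radius summary, so the package reproduces the worked-example
arithmetic (roughness 52.35 +/- 31.76 nm; accuracies 0.964 / 0.626 /
0.935; precisions 0.943 / 0.767 / 0.876; radius errors 0.46% and 3.80%;
resolution ratio 3.84) from its own functions. These tables are inputs
copied from print, not recomputed microscopy.

## Problem sizes, determinism, limitations

All shipped fixtures are at most 64^3 voxels and the complete test suite
runs in under a minute on one core; the phantom studies behind the
parameter-recovery checks (ten fiber orientations, plane fits at 2 x 10^4
points) were sized so that sampling error sits well inside the asserted
tolerances. Every stochastic stage takes an explicit seed and restores the
caller's RNG state; rendering and full pipeline runs are bit-reproducible
under a fixed seed.

Known limitations, deliberately accepted: the end-to-end contact-recovery
figure is computed with the verified (ground-truth) cell mask, mirroring
the measurement workflow in which cropping and contact extraction consume
visually verified cell segmentations — with the simplified automatic cell
mask the blur halo inflates the contact set and the overlap drops; the
Frangi filter is the standard form (the original study's "modified"
variant is not published in the main text); SC geometric contact uses the
fitted surface nearer the cell centroid, as the side the cell rests on;
and Eq.-style probability distances are computed on [0, 1] probabilities
(published distance tables on an apparent 8-bit scale are therefore not
comparable targets).
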