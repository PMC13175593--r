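---
title: "Disk harmonic flattening of cranial CT surfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disk harmonic flattening of cranial CT surfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skullflat)
```

## The problem

Skull fractures — especially in the basilar and facial regions — are easy to
miss on axial CT because the curved bone projects onto slices in which
fracture lines, sutures, emissary veins and vascular channels superimpose.
`skullflat` renders the whole cranial vault as a set of flat disk images: the
outer skull surface is extracted from the CT volume, cut into four
simply connected hemispheric patches, and each patch is flattened onto the
unit disk by a discrete harmonic map. Because the map is close to conformal,
local shape is preserved, and a fracture that crosses the bone surface
appears as a thin dark curve on a bright disk. Offset copies of the surface
at increasing depth ("subsurface layers") make the fracture's depth extent
visible layer by layer.

## Pipeline and model

### Segmentation and surface extraction

The volume (HU values) is smoothed with a Gaussian of physical scale
`sigma_mm` (default 0.5 mm, converted per axis to voxel units so anisotropic
voxels are handled correctly), thresholded at `hu_threshold` (default 300
HU, a standard lower bound for cortical bone), and reduced to its largest
connected component (26-connectivity), which removes the bed, head holder
and disconnected artifacts. Each axial slice is then closed in 2-D
(dilation by a disc of `dilate_r` voxels, hole filling, erosion by
`erode_r`; defaults 3 and 3) so that every slice becomes a solid head
cross-section whose outer contour follows the outer table of the skull.
The exposed voxel shell of this solid (true voxels with a false
face-neighbour, voxel-centre world coordinates) is the surface point cloud.

The defaults are deliberately insensitive parameters: on the bone/air and
bone/tissue contrasts of CT, any threshold in roughly 200–500 HU selects
the same shell to within a voxel. Equal dilation and erosion radii
approximate a morphological closing and preserve the outer contour scale.
Morphology is strictly per-axial-slice, reflecting how head CT is acquired
and keeping the operation cheap and predictable; no 3-D structuring
elements are used.

### Meshing at the critical alpha

The cloud is tetrahedralized (an incremental Bowyer–Watson Delaunay
implementation in C++, with deterministic symbolic jitter of about 1e-5 of
the extent to resolve the grid degeneracies of voxel clouds; the jitter is
used only inside the predicates — output coordinates are the original
points). The alpha complex at parameter alpha is the set of tetrahedra with
circumradius at most alpha. The *critical* alpha is found by bisection over
the sorted circumradius spectrum as the smallest value for which the
complex (i) is a single face-connected component, (ii) references every
input point, and (iii) has a watertight boundary — every boundary edge
bordered by exactly two boundary faces. Condition (iii) is this package's
operational reading of a shape that "encloses" its points: without it the
bisection can stop at complexes whose boundary is non-manifold debris. A
consequence worth knowing: on uniformly dense convex clouds the critical
alpha can resolve near the convex hull. For the roughly ellipsoidal outer
head surface this is the desired answer; strongly concave anatomy would
rely on locally denser sampling. The returned surface is the largest
connected boundary component (for a thin shell: the outer one), cleaned to
an edge-manifold mesh (faces on over-shared edges dropped smallest-area
first), consistently wound outward, and optionally refined by one round of
Loop subdivision (default 1, configurable 0–2) for curvature continuity.
Subdivision is applied before partitioning, so all four views share one
refined geometry.

### LUFO partition

Four views — lower, upper, frontal, occipital — are cut by two orthogonal
centroid planes derived from principal axes of the vertex cloud: the axis
of largest extent is taken as antero-posterior, and the remaining principal
axis most aligned with the volume's axial direction as superior-inferior.
No image registration is required; only the half-space assignment depends
on orientation, and the sign convention (superior towards +z, anterior
towards +y) matches RAS-oriented volumes. Each half is widened by
`overlap_fraction` (default 0.1) of the extent along its split axis — half
the band on each side of the plane — so a fracture near a cut remains fully
visible in at least one adjacent view; because the two cut directions are
orthogonal, no fracture can be interrupted in all four views at once. A
face is kept when all three vertices are kept (clean patch boundaries);
the patch is reduced to its largest edge-connected component and validated
as a topological disk (one boundary loop, edge-manifold, V − E + F = 1).

### Disk harmonic map

The single boundary loop of a patch is traversed from the lowest-index
boundary vertex in the direction induced by the face winding. With
edge lengths `s_v` along the loop, vertex `v` receives the angle
`theta_v = 2 * pi * cumsum(s)_v / perimeter` and the circle position
`z_v = exp(1i * theta_v)` — arc-length parametrization of the boundary onto
the unit circle. The cotangent Laplacian has off-diagonal weights
`w_ij = (cot(alpha_ij) + cot(beta_ij)) / 2` over the one or two angles
opposite edge (i, j), and diagonal equal to the negated row sum. Interior
rows of the linear system keep the Laplacian with zero right-hand side;
boundary rows are replaced by identity with `z_v` as data (Dirichlet
constraints) — the unique well-posed form of inverting the constrained
Laplacian, since the unconstrained operator has a null space. One sparse LU
factorization solves both coordinates; there is no iterative tolerance, so
results are deterministic to machine precision. Negative weights from
obtuse triangles are kept as written — clamping would silently change the
operator; instead, flipped facets are counted and reported. For weights
that are all non-negative the discrete maximum principle guarantees every
interior image strictly inside the disk and an injective map.

The absolute rotation of each disk is a free parameter of the method (the
anchor and orientation convention fixes it reproducibly, lowest boundary
index at angle 2π, counterclockwise image); only rotation-invariant
quantities should be compared across implementations.

### Subsurface layers

Per-vertex outward normals are area-weighted averages of incident face
normals. Skull thickness is estimated by marching each vertex inward along
its normal in steps of half the minimum voxel dimension until HU drops
below the bone threshold or `max_depth` (default 20 mm) is reached; the
summary is the 95th percentile of per-vertex depths, which resists deep
outliers (mastoid air cells, foramina) better than the maximum. Layer k
places every vertex at `base − k * spacing * normal` with spacing equal to
the minimum voxel dimension, sampling HU by trilinear interpolation; all
layers share the base connectivity and therefore the base flattening, so a
pixel addresses the same anatomical column at every depth. Offsets are pure
normal displacements — no remeshing; fold-overs possible at high curvature
are counted per layer (`folded_faces`), not repaired. Layer HU is sampled
at the offset positions rather than re-extracting intensity isosurfaces;
that is the operational meaning of "points perpendicularly below the outer
surface".

### Distortion metrics

Per facet, the three corner angles `acos(u . v / (|u| |v|))` are compared
between the 3-D patch and its planar image; the facet's angle error is the
mean absolute difference in degrees (all three corners, since any two edge
vectors determine the triangle). Area error is `log10(A_image / A_surface)`
per facet, base 10 so the values read as orders of magnitude; a natural-log
option exists. The raw ratio carries a constant offset — the unit disk's
total area over the patch's total area in mm² — so the report also provides
`E_A_norm` with that total-area ratio removed, a pure local distortion
centred at 0. Facets whose image is flipped relative to the dominant
orientation are measured on |A| and flagged; zero-area source facets are
excluded and counted. Whether flipped facets should be excluded from
histograms is left to the reader — here they are included and flagged.

### Rendering

Image triangles are rasterized into a square grid over [−1, 1]² with
barycentric interpolation of vertex HU; where triangles overlap (flipped or
folded geometry) the pixel keeps the maximum, so bone signal cannot be
hidden by a fold. Maximum and average intensity projections combine the
per-layer rasters pixel-wise over the layers that cover the pixel.
Window/level display mapping is linear to 8-bit with clamping; exact
half-points round half-down (window centre maps to 127). Default raster
resolution is 1024 px per disk diameter and the default display window is
centre 500 / width 2500 HU, both configurable.

## The synthetic phantom

The phantom emulates the features of head CT this pipeline actually
consumes: a closed, roughly ellipsoidal bone shell (default semi-axes
65/55/70 mm, thickness 6 mm, constant or smoothly varying) at bone HU
(default 1200) over a soft-tissue interior (40 HU) and air background
(−1000 HU), with additive Gaussian noise (default SD 20 HU, typical of head
CT) under a fixed seed, and optional defects: planar fracture slits
(optionally depth-limited from the outer surface and restricted to an
angular window), suture-like slabs, and cylindrical vein channels — the
confounders that make fracture reading hard. Ground truth (analytic signed
distance to the outer surface, exact defect masks, shell voxel count) is
returned alongside the volume, so every stage is testable without patient
data.

What the phantom does not emulate: realistic cranial anatomy (foramina,
mastoid air cells, sutural bones, table/diploe layering), beam-hardening
and streak artifacts, and a non-convex outer head contour. Passing tests on
the phantom therefore demonstrate the geometric and numerical correctness
of the pipeline under known conditions, not segmentation robustness on
clinical data.

## Numerical choices

* Delaunay predicates are double-precision determinants guarded by an
  error filter (sum of absolute expansion terms); ties fall to the
  deterministic jitter. The triangulation was validated against an
  independent implementation on random clouds (exact simplex agreement).
  If the tet adjacency graph comes out disconnected or a point is skipped
  — the signature of a predicate failure on near-degenerate input — the
  jitter is escalated (1e-5, 1e-4, 1e-3 of the extent) and the
  tetrahedralization rebuilt, still deterministically.
* Bisection over the circumradius spectrum is a finite search; it
  terminates when adjacent spectrum values bracket the predicate.
* The harmonic solve uses a sparse direct factorization (Matrix package);
  agreement with a dense solve is part of the test suite at 1e-8.
* Zero-area faces are dropped at cleanup with an area tolerance relative
  to the mesh extent (1e-12 × extent²); zero-length edges are hard errors
  in the Laplacian and angle computations.
* Ray marching steps at half the minimum voxel dimension; rays leaving the
  volume stop there (outside samples take the volume minimum).
* Tie-breaks are deterministic everywhere: equal-size components resolve
  to the lowest linear voxel index; the boundary anchor is the lowest
  vertex index; bisection returns the smaller bracketing spectrum value.

## Problem sizes used in the tests

The default test phantoms are 72³–112³ voxels at 1–1.5 mm spacing with
~15–25k surface points, and the full-pipeline checks run at raster
resolution 384; the flattening proxy uses a 20k-face analytic hemisphere.
These sizes exercise every code path at full fidelity while keeping the
whole suite in the tens of seconds on a single CPU; all quantities reported
by `scripts/acceptance.R` are recomputed at run time at these sizes.

## Known limitations

* The watertight-boundary reading of the critical alpha favours the outer
  envelope on uniformly sampled convex clouds; deep concavities (e.g. the
  orbits if they survive the per-slice closing) may be bridged.
* Normal-offset layers do not follow the bone's internal trajectory where
  thickness varies quickly (mastoid); thickness is a global summary.
* Anatomical naming of the four views assumes an approximately
  RAS-oriented volume; arbitrary patient orientations permute the labels
  but not the geometry.
* DICOM support is a minimal single-series reader (uncompressed
  little-endian explicit/implicit VR); compressed transfer syntaxes are
  rejected explicitly. NIfTI is the primary interchange format.
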