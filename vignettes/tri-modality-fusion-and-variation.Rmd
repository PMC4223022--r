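---
title: "Tri-modality image fusion and delineation-variability metrics: methods"
author: "trifuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-modality image fusion and delineation-variability metrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trifuse)
```

## The problem

Delineating the gross tumor volume (GTV) for radiotherapy planning of brain
tumors draws on complementary image modalities: CT shows bone and electron
density, contrast-enhanced T1 MRI shows the enhancing lesion, and
^18^F-FDG PET shows metabolic activity. Clinicians conventionally flip
between side-by-side panels; a transparency-weighted fusion instead blends
all three co-registered volumes into one panel whose mixing weights the
clinician adjusts continuously. The companion question is quantitative: does
adding PET to an MRI/CT workflow make different observers (or the same
observer at different times) agree more? `trifuse` implements both halves —
the fusion operator and a variability pipeline of volume statistics,
surface-shape statistics and local surface-distance maps — plus a synthetic
phantom generator so the entire pipeline is exercised without clinical data.

## The fusion model

With CT as the opaque background and MR, then PET, as semi-transparent
foreground layers, back-to-front alpha compositing gives the fused intensity

$$I_{mix} \;=\; t_P\, I_{PET} \;+\; (1 - t_P)\,\bigl[\, t_M\, I_{MR} + (1 - t_M)\, I_{CT} \,\bigr],$$

where $t_P, t_M \in [0,1]$ are the PET and MR transparency factors. We
follow the panel convention in which $t = 1$ fully shows a layer (an
opacity-like weight): $(t_P,t_M) = (0,0)$ is pure CT, $(0,1)$ pure MR, and
$t_P = 1$ pure PET regardless of $t_M$. The three effective weights
$t_P$, $(1-t_P)t_M$ and $(1-t_P)(1-t_M)$ are nonnegative and sum to one, so
every fused voxel is a convex combination of its inputs — the output stays
in $[0,1]$ over the whole $(t_P,t_M)$ square, including settings like
$(0.7, 0.7)$ where a naive additive blend
$t_P I_{PET} + t_M I_{MR} + (1{-}t_P{-}t_M) I_{CT}$ would go negative. This
sequential-compositing form was a genuine design choice: checkpoint blends
at the corner settings constrain but do not uniquely determine the
operator, and the convex form is the one that behaves for all admissible
transparency pairs.

Fusion mixes modalities with incommensurate units, so inputs must first be
window-normalized to a common $[0,1]$ scale. `windowNormalize()` maps
$[\mathrm{level}-\mathrm{width}/2,\ \mathrm{level}+\mathrm{width}/2]$
affinely onto $[0,1]$ with clipping. Defaults: CT bone window
(level 600, width 2800 HU; a brain window 40/80 is also provided), while MR
and PET — whose intensity scales are not standardized — use a robust window
spanning the 1st–99th percentile of nonzero voxels. These are deliberate
package choices (clinical practice fixes only the CT window); all windows
are overridable per call or via the CLI config.

## Geometry conventions

Volumes live on axis-aligned grids with a voxel-center convention: the
world coordinate of 0-based index $i$ is $\mathrm{origin} + i \cdot
\mathrm{spacing}$ (mm, right-handed axes). Registration is out of scope —
head image sets are well served by rigid alignment and the transform is an
input (a plain-text 4×4 matrix), applied by `resampleToGrid()` with
trilinear interpolation for images and mandatory nearest-neighbor for
masks. Out-of-field voxels are filled with a neutral background per
modality (CT −1000 HU, MR/PET 0). Distances are computed in mm and
reported in cm, volumes in cm³, matching clinical reporting.

## Delineation variability metrics

**Volume COV.** For each structure the coefficient of variation of the
observers' volumes is the sample SD (n−1 denominator) over the mean. The
n−1 convention is not arbitrary: feeding the bundled per-observer GTV
volumes through `covReport()` reproduces every printed per-patient COV of
the reference tables after 2-decimal rounding, whereas the population-SD
variant fails (patient 1, dual-modality: 0.06 vs the printed 0.07). The
test suite carries this discriminating check.

**ADSC.** Each observer mask is meshed and the average distance between
surface and centroid is the unweighted mean, over all triangles, of the
Euclidean distance from the triangle barycenter to the mask centroid
(in cm). "Its centroid" is read as the structure's centroid — the only
reading under which ADSC is a size/shape descriptor (a triangle's distance
to its own centroid is zero). Whether the original metric area-weighted the
triangles is unstated; the unweighted mean is the default and
`areaWeighted = TRUE` is exposed. For a sphere ADSC converges to the
radius; the suite requires agreement within 1% for a 1 cm digitized sphere
at 1 mm spacing.

**Median surface.** The 50% coverage-probability volume keeps every voxel
covered by at least half of the observer masks (ties kept, so with three
observers it is the majority vote); its iso-surface is the median surface.
`coverageVolume()` is monotone in the threshold, with the union and the
intersection as its limits.

**SD_local.** From every vertex of the median surface, a bidirectional ray
along the outward unit normal is intersected with each observer's surface;
the intersection with the smallest absolute ray parameter within a 50 mm
cap gives a signed perpendicular distance (positive when the observer
surface lies outward). The per-vertex sample SD of these distances is
SD_local (cm), attached to the median mesh as the `"sd_local"` attribute
and exportable to PLY for color-wash rendering. Signed distances are the
default because the underlying median-surface methodology uses signed local
deviations; an unsigned variant is exposed by flag. Rays that miss within
the cap (open or highly irregular geometry) fall back to the nearest-point
distance signed by an intersection-parity inside/outside test; the fallback
rate is reported and logged.

**Octants.** The median surface is split into eight regions by the octants
of a coordinate system whose origin is the mean of the observer-mask
centroids and whose axes are the world axes. The numbering convention is
declared (label $= 1 + [x<O_x] + 2[y<O_y] + 4[z<O_z]$, boundary coordinates
to the "≥" side) because no standard numbering exists; octant identities
are reportable but not comparable across software. SD_local is averaged
per octant and over all vertices (the overall mean is over every vertex,
whether or not some octant is empty).

**Paired tests.** Scheme comparisons use the classic paired two-tailed
t-test (`stats::t.test`) with df = n−1 and a 95% CI; zero-variance
differences return a degenerate flag rather than a spurious p-value. On the
bundled intra-observer COV table the 95% CI of the dual-vs-tri difference
rounds to [0.01, 0.06].

## Surface extraction

No installed iso-surfacing library was available, so `extractSurface()`
implements tetrahedral-decomposition iso-surfacing, a watertight member of
the marching-cubes family: each cell of 8 voxel centers is split into six
tetrahedra around the main diagonal and each tetrahedron is triangulated
independently at the 0.5 iso-level of the binary field. The 6-tet split
triangulates every cell face with the same diagonal as its neighbor, so the
mesh is closed by construction and none of the ambiguous cube cases arise.
Crossing vertices sit at edge midpoints (exact multiples of 0.5 in index
space), making vertex welding exact; masks are padded by one background
voxel so structures touching the grid boundary still close; no smoothing is
applied (reproducibility over cosmetics). Triangle orientation is fixed
per-tetrahedron so face normals point from inside to outside, and enclosed
volume (divergence theorem) is positive.

Vertex *normals*, however, are not taken from face windings: on a binary
staircase surface winding normals oscillate tens of degrees about the true
surface direction, which inflates normal-ray distances (a ray at angle
$\alpha$ to the true normal crosses a parallel surface at distance
$d/\cos\alpha$). Instead, normals follow the gradient of the
$[1,2,1]/4$-smoothed binary field, trilinearly sampled at each vertex — the
classic marching-cubes normal estimate. On concentric digitized spheres
(radii 8/10/12 mm, 1 mm spacing) this brings mean SD_local to within 1% of
the closed-form SD of (−2, 0, +2) mm, where winding normals leave a ~12%
bias.

## The phantom generator

`generatePhantom()` builds a head-like scene: an air background (−1000 HU)
with a soft-tissue head sphere and a bony skull shell on CT; a uniform
brain with a lesion whose rim is contrast-enhanced on MR; uniform brain
uptake with focal lesion uptake (default lesion-to-background ratio 4) on
PET; plus additive Gaussian noise per modality (defaults 5 HU, 10 a.u.,
0.05 relative). The ground-truth GTV is the exact digitization of an
ellipsoidal lesion (default semi-axes 20/16/18 mm on a 128³ grid at 2 mm —
the scale of a clinical planning CT; tests and the acceptance script use
64³ grids, which hold the same lesion with identical geometry at a fraction
of the cost).

`simulateObservers()` stands in for human observers: each observer's mask
keeps the voxels whose signed distance to the truth boundary lies below a
smooth random radial displacement field plus a per-observer systematic
margin. The fields are band-limited real spherical-harmonic expansions
(default band limit 4) with i.i.d. Gaussian coefficients; by the addition
theorem, equal per-band variance makes the pointwise displacement SD
uniform on the sphere and exactly equal to the requested `radialSdMm`. The
signed distance is an exact Euclidean distance transform of voxel centers
with a quarter-voxel digitization offset, chosen so that thresholding at a
margin $m$ reproduces the analytic dilation and erosion radii without
systematic drift in either direction (a +2 mm margin on a 20 mm sphere
lands within ~1% of the 22 mm analytic volume; half-voxel or zero offsets
bias one direction by 4–8%). All randomness flows from one integer seed
with per-observer sub-seeds `seed + observer`.

What the phantom does *not* emulate: PET partial-volume and point-spread
blur, MR bias fields, anatomy-correlated observer disagreement (real
observers err systematically near ambiguous tissue interfaces, not
isotropically), and inter-modality misregistration. Passing tests therefore
demonstrate the correctness of the *metrics* under controlled disagreement,
not clinical performance claims.

With the defaults, injected 2 mm radial SD across 3 observers is recovered
by the pipeline's mean SD_local at about 1.4–1.5 mm. The shortfall is
expected: the median surface itself absorbs part of the disagreement, and
smooth fields correlate the three distances at each vertex; mean SD_local
is a biased (shrunken) estimator of the injected radial SD. The suite
asserts recovery within [1, 3] mm and that volume COV increases
monotonically with the injected SD.

## Numerical choices and degenerate inputs

- Binary masks are meshed at iso 0.5 exactly; no pre-smoothing.
- Normal-ray cap 50 mm; beyond it the flagged nearest-point fallback keeps
  SD_local defined everywhere.
- Self-distance of a mesh to itself is zero to well below 1e-6 mm.
- Empty masks: surface extraction, centroid and observer simulation raise
  informative errors; COV of a zero-mean sample and zero-variance paired
  differences return flagged results instead of errors.
- Coverage threshold comparisons use a 1e-12 slack so exact 50% ties are
  kept regardless of floating-point representation.
- Grid equality for voxelwise operations is exact in shape and within
  1e-6 mm in spacing/origin.

## Problem sizes

The test suite runs digitized spheres on 32–48³ grids at 1 mm and phantoms
on 24–64³ grids at 2 mm; the acceptance script uses 64³ phantoms, 10 seeds
for SD_local recovery and 3×5 seeds for the COV-monotonicity check. These
sizes keep the full suite to a few minutes while leaving every oracle's
tolerance comfortably resolved; all operators scale to clinical 512×512×224
grids linearly in voxel count.

## Known limitations

- The fusion operator is scalar (grayscale), matching the intensity-space
  definition; pseudo-color PET overlays are presentation, not computation,
  and are not implemented.
- Ray-mesh distance is brute force over triangles — ample for the mesh
  sizes here (≤ ~10⁴ faces); very dense clinical meshes would want a BVH.
- The NRRD reader covers the subset this pipeline writes (3D scalar,
  raw/gzip, attached data); NIfTI via RNifti is the primary format.
- Octant numbering is a declared convention; comparisons of individual
  octants against other software's "quadrant" tables are not meaningful,
  only the overall and per-region summaries are.
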