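---
title: "Methods: hybrid voxel/mesh modeling of DIEP-flap print models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid voxel/mesh modeling of DIEP-flap print models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`voxflap` rebuilds, as a scriptable library, the workflow that turns an
abdominal CT angiogram into a multi-material 3D-printed planning model for
DIEP (deep inferior epigastric perforator) flap surgery. This vignette
explains the model behind each stage, the parameters that matter, the
numerical choices, and what the synthetic phantom does and does not
demonstrate.

## Segmentation as effective thresholding

Clinical practice segments each structure by its Hounsfield range: contrast
under arterial phase puts vessel lumina far above soft tissue, and muscle
occupies a narrow band above fat. We implement segmentation as the
*effective behavior* of that workflow: an inclusive window
`hu_lo <= HU <= hu_hi`, optional Gaussian smoothing of the binary mask
(re-binarized at 0.5), and removal of connected components (26-connectivity)
below a voxel count. A full curvature-driven level-set evolution is
deliberately out of scope: the windows are what parameterize the published
workflow, and the smoothing term reproduces its regularizing effect. Both
window bounds are inclusive — "between 180 and 230 HU" reads naturally as a
closed interval, and the test suite pins that convention.

The vessel window need not be guessed: `sample_reference_range()` mirrors
sampling the descending aorta, returning `mean ± half_width`. The default
`half_width = 100` HU turns a 1000 HU aortic sample into the 900–1100 HU
window used for the vessel tree. Whether that window should adapt along the
vessel as contrast dilutes is left to the user (it is a plain parameter);
the default phantom draws vessel HU well inside the window so the question
does not arise in testing.

Manual editing — gap filling where a vessel fades between slices, and
restoring the muscle solid where contrast-filled lumina punched holes in
the thresholded mask — is replaced by *scripted brush strokes*: capsule
sweeps (polyline plus radius) recorded in the configuration. This keeps
runs reproducible and auditable where an interactive session would not be.
The repaired muscle is the conceptual "base model": vessel voids are then
*created* by the subtraction layer, matching the modeled-base-plus-Subtract
structure of the original workflow.

## The multi-channel voxel engine

The compositing substrate is a grid with one shape channel `s(v) in [0,1]`
and named material channels `m_i(v) in [0,1]`, with the invariants that the
per-voxel material sum never exceeds 1 (+1e-6) and that material weight is
zero wherever shape is zero. Layers evaluate strictly bottom-up:

* `replace` — the base layer sets the shape;
* `subtract` — `s <- max(0, s - l)`: voids, e.g. vessels out of muscle;
* `add` — `s <- min(1, s + l)`: e.g. support struts;
* `material_add` — writes weight into one material channel, clamped to 1,
  with competing channels scaled down proportionally; the shape channel is
  returned bit-identical.

Boolean layers operate on occupancy binarized at 0.5. The shape channel is
typed as a density to admit anti-aliased sources, but the published
operations are boolean ("subtract ... to create voids"), so binarization is
the default and the only mode exercised by the tests.

Two semantics are offered for material accumulation because the source
workflow describes both an "additive arithmetic" composite and a grid layer
that "supersedes" the base voxels. `material_add(..., combine = "add")` is
the accumulating form; the measured-grid overlay instead uses
`combine = "max"` (supersede), which is idempotent — stamping the grid
twice equals stamping it once — and is what a deterministic pipeline wants
from an overlay. This is a documented reconstruction: the original tool's
exact clamping arithmetic is not published.

Vessel classification is containment: vessel voxels where the
*pre-subtraction* muscle shape exceeds 0.5 are intra-muscular, the rest
extra-muscular. The two masks partition the vessel support by construction,
and the classification grid is aligned to the volume lattice so no
resampling error enters.

## The measured grid

Two orthogonal families of parallel world-space planes, spaced
`spacing = 10` mm, with one plane of each family through the anchor (the
umbilicus centroid, resolved from the umbilicus mask when the config says
`auto:umbilicus`). Each plane carries a linear halo

```
f(d) = strength * max(0, 1 - d / falloff)
```

with `strength = 1` (100%) and `falloff = 1` mm by default. The linear
profile with support radius equal to the falloff is the unique simple
reading under which a 1 mm falloff yields the published 2 mm band width
(zero crossing to zero crossing), independent of spacing and strength.
Families combine by maximum, not sum, so band crossings never exceed
`strength` (and the per-voxel material-sum invariant is safe). Planes are
flat world-space planes, not geodesics on the muscle surface: the grid
marks the muscle where the planes intersect its volume, which matches the
straight ruled bands of the printed models; surface-conforming grids are a
non-goal. Perforators map to grid cells by `floor(offset / spacing)` per
axis — half-open, 0-based, anchor-centered cells — with offsets also
reported in cm to one decimal.

## Meshing: marching tetrahedra, watertight by construction

Isosurfaces are extracted at level 0.5 — the midpoint between material
absent and full — by marching tetrahedra on the Kuhn 6-tetrahedron split of
each lattice cube. Within a tetrahedron the iso-contour is unambiguous, the
split is consistent across shared cube faces, and iso-vertices are keyed by
the lattice edge they sit on (welded by construction), so every surface is
closed and manifold without ambiguous-case patching; a one-voxel virtual
zero layer caps any support that touches the grid border. Triangle
orientation is fixed per-element by pointing the normal from the inside
corners toward the outside corners, and `check_watertight()` verifies zero
open edges, zero non-manifold edges, zero flipped-winding pairs and
positive signed volume for every exported mesh.

Extraction from binary data facets the surface and slightly biases volume;
optional Gaussian pre-smoothing (`smooth_sigma`, default 0.5 voxel)
suppresses both. Conservation-sensitive tests run with smoothing off: there
a binary sphere of radius 5 mm at 0.5 mm voxels meshes to within 2% of
4/3·π·5³, and a 10 mm capsule of radius 1.5 mm at 0.25 mm voxels to within
3% of its analytic volume — tolerances pinned from pre-build measurement
runs (observed errors were 0.6% and 1.0%). The capsule is measured at
0.25 mm because a 1.5 mm radius spans only three 0.5 mm voxels, where
lattice quantization alone moves the cross-section area by over 10%.

`split_by_material()` quantizes voxels by material fraction against a
threshold (default 0.5) inside the shape support and extracts both parts
without smoothing, so the voxel supports partition the shape support
exactly and the shared interface surfaces coincide. Mesh voxelization (the
inverse map, used by the round-trip tests) classifies voxel centers by
parity ray casting along +x; rays carry a fixed, documented sub-voxel
offset (≈0.21 and 0.18 voxel in y and z) so they cannot strike triangle
edges or vertices — a deterministic symbolic-perturbation stand-in for
random jitter.

## The phantom: what it emulates, and what it does not

The phantom emulates the geometry and contrast structure an abdominal CTA
contributes to this workflow: a curved muscle slab (HU uniform in
[190, 220], inside the 180–230 window) spanning the volume; a vessel trunk
running inferior–superior beneath the slab with a sinusoidal lateral
wobble (`tortuosity`, default 2 mm), sending perforators vertically through
the slab (HU in [950, 1050]); an umbilicus cone anterior to the slab (HU
in [30, 50]); fat background `N(-75, 10)` HU, giving unambiguous separation
from both printed tissue windows (no published fat window exists — fatty
tissue was dropped from the final printed models — so this is a free
choice); optional additive Gaussian noise, applied last; and an optional
superficial (SIEA-like) vessel that never enters the muscle. The default
volume is 128×128×96 voxels at 1 mm — small enough that the full reference
pipeline runs in about two minutes on one CPU, large enough that every
compositing path (subtraction void, material overlay, containment split,
strut) is exercised.

The vessel tree is a scripted template, not a stochastic growth model,
because the ground truth must be exact. Perforator sites are placed on the
flat central region of the slab's bulge, where the digitized anterior
surface is locally level; the generated repair strokes exploit this: the
brush radius `r_b` solves `r_b - sqrt(r_b² - r_v²) = 0.4·h` (with `r_v` the
perforator radius and `h` the voxel size) and the stroke endpoints retract
from the slab faces by `r_b - 0.75·h`, so the swept capsule covers exactly
the tunnel voxels inside the slab and only slab voxels outside the tunnel.
The filled muscle then equals the geometric slab voxel-for-voxel, which is
why noise-free recovery and intra/extra classification achieve Dice = 1.0
as an exact identity rather than a toleranced approximation.

What passing these tests does *not* show: real CTA brings partial-volume
boundaries, contrast gradients along vessels, beam hardening, motion, and
anatomy far less separable than uniform HU draws; on such data the
thresholds, smoothing and manual-edit scripts all require judgment. The
phantom validates the machinery — the compositing algebra, the geometry
kernels, the bookkeeping — not the clinical segmentation problem.

Under noise the recovery degrades as expected: with mask smoothing of 1 mm
and a 27-voxel component filter, segmentation Dice on a 64×64×48 phantom
stays above 0.95 (muscle) and 0.89 (vessels) at noise σ = 20 HU — bounds
pinned from a pre-build oracle run over five seeds — and mean Dice is
non-increasing across σ ∈ {0, 10, 20, 40} HU.

## Numerical and design choices

* **Geometry conventions.** World units are mm everywhere; voxel centers at
  `origin + (index - 1) * spacing`; grids are isotropic with a 0.5 mm
  default voxel (a band spans four voxels; 1 mm vessel radii stay
  representable) and 2 mm default padding so isosurfaces close at the
  border.
* **Resampling.** Masks move onto grids by nearest neighbor; the pipeline
  only ever uses volume-aligned grids (equal or integer-refined spacing),
  where nearest neighbor is exact, so recovery tests measure the method,
  not interpolation.
* **DICOM intake** is a minimal reader for uncompressed single-frame scalar
  CT series (explicit/implicit VR little endian, rescale slope/intercept
  applied, axis-aligned orientation enforced, heterogeneous series
  rejected); NIfTI I/O goes through RNifti. The reader is cross-checked in
  the tests against series written by an independent implementation
  (pydicom).
* **Degenerate inputs.** All-zero segmentations are valid results
  (with a warning); empty masks yield valid empty grids; an empty material
  remainder after splitting is a legitimate empty mesh, while extracting an
  empty channel is an error; zero-length struts and coincident stroke
  radii are rejected at construction.
* **Determinism.** The phantom is bit-reproducible from its seed (RNG state
  is saved and restored); voxelization jitter is a fixed constant; reruns
  of the pipeline with the same config and seed produce byte-identical
  STL files, and the manifest embeds the MD5 of the canonical JSON form of
  the configuration.
* **Test problem sizes.** Property tests run on 64×64×48 phantoms and
  random 16³–32³ grids; the acceptance suite runs the full default
  128×128×96 phantom end to end. These sizes were chosen as the smallest
  that exercise every code path at full fidelity.

## Known limitations

No mesh-domain booleans (the voxel engine is the point), no GPU paths, no
multi-phase registration or MRA support, no surface-parameterized grids, no
automatic strut placement (struts come from the config, as the original
supports were placed by hand), and no 3MF/AMF multi-material containers:
STL carries no color, so material assignments live solely in the JSON
manifest, mirroring slicer-side assignment. The intra-muscular band mesh
and muscle remainder are exported as separate parts; whether to union them
at print time is left to the slicer.
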