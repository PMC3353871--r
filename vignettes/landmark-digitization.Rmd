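---
title: "Digitizing 3D landmarks on volumetric CT data with voxmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing 3D landmarks on volumetric CT data with voxmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxmark)
```

## The problem

Geometric morphometrics builds shape analyses on the 3D coordinates of
biologically homologous landmarks, digitized on micro-CT scans of skulls and
other structures. Type-3 (extremal) landmarks — "the anterior-most point of
a suture", "the tip of the coronoid process" — are only well defined
relative to a viewing geometry, which makes their repeated digitization the
hardest part of the job. voxmark is a headless, scriptable toolkit for this
task: it loads DICOM slice stacks into a voxel volume, renders the volume by
ray casting, maintains one synchronized 3D cursor shared by the rendering
and three orthogonal cross-sections, places that cursor on the first
supra-threshold structure under a screen pixel, offers symmetry-plane and
axis geometry to pin viewing directions down exactly, and exports TPS/NTSYS
coordinate files for downstream software (the IMP series, MorphoJ, R shape
packages). Everything interactive in a GUI-based workflow is expressed here
as a replayable session script, so a digitization is a reproducible record
rather than a sequence of mouse events.

## Volumes, conventions, degenerate inputs

A `volume` is a 3D array of double intensities with voxel `spacing`
(physical units per voxel, strictly positive), an `origin`, and provenance
of any down-sampling. One convention is stated once and asserted everywhere:
voxel indices are 0-based, `x` is the column axis, `y` the row axis, `z` the
slice axis, and an index refers to the voxel *center*, so
`world(i,j,k) = origin + (i*sx, j*sy, k*sz)`. The volume's world-space
support is taken to be the voxel-center bounding box; cursor positions are
clamped to it, and rays enter and exit the volume at its faces. Trilinear
interpolation clamps query points to this box, so border queries return
border-voxel values rather than extrapolating.

Down-sampling by block averaging (`downsample`) reduces both rendering cost
and noise. Each output voxel is the equal-weight mean of a full
`fx × fy × fz` block; trailing voxels that do not fill a block are dropped
(`floor(dims/factors)`), which keeps every output voxel an unweighted mean —
averaging partial blocks would silently change the noise properties of edge
voxels. Factors may differ per axis. Spacing multiplies by the factors and
the origin moves to the first block's center, which the voxel-center
convention forces. A 658 × 658 × 1000 micro-CT stack at factor 2 becomes
329 × 329 × 500.

DICOM slices are sorted into anatomical order by InstanceNumber when
present, else by slice position, else by file name, so shuffled directory
listings load identically. Rescale slope/intercept are applied on load and
intensities kept as doubles from then on. Files lacking spacing attributes
are an error with an explicit `spacing_override` escape hatch, not a guess.
The bundled DICOM *writer* is a test-fixture generator (single-frame,
uncompressed, explicit VR little endian, signed 16-bit) — enough for
lossless round trips of integer-valued phantoms, and deliberately not a
clinical writer.

## The rendering model

Volume rendering assigns each sample an opacity from its intensity and a
reflectivity from its intensity gradient, then composites shaded samples
along view rays — every voxel can contribute, which is what avoids the two
classic failure modes of thresholded surface rendering (noise when the
threshold is too low, non-physical pseudo-fenestrations where it is locally
too high).

The parameters that matter:

* **Opacity ramp** (`transfer_function`): piecewise linear in intensity,
  0 below `low_intensity`, `max_opacity` at/above `high_intensity`
  (intensity units are whatever the scan stores). A steep ramp isolates one
  surface ("surface" mode); a low plateau over a broad band renders all
  surfaces translucently at once.
* **Reflectivity**: `clamp(reflectivity_gain * |∇I| / max|∇I|)`, the
  gradient norm normalized over the volume so the transfer function is
  independent of intensity units. Gradients are central differences scaled
  by 1/spacing per axis (one-sided at borders), sampled trilinearly from
  precomputed component grids during rendering.
* **Shading**: ambient plus Lambertian diffuse,
  `(ambient + Σ_l I_l · colour_l · refl · max(0, n·L_l)) · base_colour`,
  channel-clamped. The surface normal is the negated unit gradient (bright
  structures on dark background). No specular term: gradient-driven
  "reflectivity" is a diffuse gain, and a minimal, parameter-free shading
  model keeps picking geometry the star of the show. Pseudo-colour output
  is the same machinery with a background colour and a foreground tint.
* **Camera** (`view_state`): an orthographic right-handed orthonormal frame.
  Orthographic, not perspective, because landmark picking requires each
  pixel to define exactly one world ray.
* **Ray step**: `0.5 * min(spacing)` — sub-voxel sampling without excessive
  cost. Compositing is standard front-to-back over-compositing with early
  termination at accumulated opacity 0.999; residual transparency is filled
  with the background colour.

Pixel centers are laid out symmetrically about the view center
(`(col − (w−1)/2) · pitch` along screen x), so the center pixel of an
odd-sized image maps exactly onto the view center and mirror-symmetric
scenes render to mirror-symmetric images — the property the geometry tests
rely on. The brute-force ray caster is the package's reference renderer;
an accelerated shear-warp path was considered and not implemented, since
the reference renderer already handles desk-scale volumes in well under a
second and a second renderer would add only an equivalence obligation.
Renderer consistency is instead checked by 90° symmetry rotations of a
rotation-symmetric phantom (tolerance 5/255 per channel).

## Picking: from pixel to first structure

`screen_ray` maps a pixel to its orthographic world ray; `first_hit`
marches that ray from volume entry at the render step, testing the
trilinearly interpolated intensity against a strict `> threshold`, then
refines the first bracketing step by bisection to 10⁻³ voxel along the ray
— sub-voxel landmark precision is the point of the tool. A threshold below
the volume minimum returns the entry point; a ray that misses the volume
and a ray that never exceeds the threshold both yield no hit (distinguished
in the session log). There is deliberately **no default threshold**: bone
intensity is scanner- and protocol-dependent, so the threshold is an
explicit user parameter, with a phantom-calibrated example preset shipped
under `inst/extdata/`.

Two numerical choices deserve a note:

* Interpolated picking is cross-checked in the tests against an independent
  fine-step traversal oracle (0.05 voxel steps, linear crossing
  interpolation) — hit voxels must agree exactly on 100-ray batteries.
* The phantom intensities are 0/40/100. A threshold of exactly 50 is the
  midpoint of the 0→100 edge, which places every trilinear crossing
  *exactly* on a half-voxel boundary — the one configuration where
  "nearest voxel" is ill-posed and two correct algorithms can round apart.
  Oracle-agreement batteries therefore use 60 (a generic, non-midpoint
  threshold); semantic checks (first-structure, monotonicity) keep 50.

Raising the threshold never moves a hit closer to the viewer, and on a
volume where an outer and an inner shell both exceed the threshold the hit
is always on the outer shell — a picked landmark passes through air and
soft tissue and lands on the first bone-like structure.

## Cursor, slices, geometry aids

A session owns exactly one cursor; picking, slicing, marking and jumping
all read and write that instance, which is the synchronization contract a
four-view GUI enforces visually. Slices through the cursor are aligned with
the volume's major axes (view rotation lives only in the renderer) and
interpolate trilinearly, so sub-voxel cursor refinement is visible in them.
Cursor moves are in voxel units with a sub-voxel-capable step.

For bilateral structures, a plane is defined by three landmarks (the
sagittal plane, anchors PL1–PL3) and an axis by two points (A1–A2, which
may reuse plane points). The normal follows the cross-product convention
from the user's point order; `reflect_point` is sign-invariant, and view
alignment takes a `flip_normal` option since the data never say which side
of the sagittal plane should face the camera. Reflection
`p − 2(n·p − d)n` is an involutive isometry to 10⁻⁹ over random
configurations; `rotate_to_plane` preserves the current up-vector as far as
possible (minimal rotation, falling back to world z then y);
`rotate_to_axis` makes the plane normal the viewing direction and the
projected axis the screen-x direction, with frames orthonormal to 10⁻¹².
Plane and axis are recomputed eagerly whenever an anchor changes, and the
recomputation is logged.

## File formats

Landmark definition files are plain UTF-8 text — one `number [type=N]
description` per line, numbers contiguous from 1, `#` comments allowed; the
symmetry map uses `midline ...` and `pair L R` lines. TPS export uses the
3D `LM3=` dialect with world-unit coordinates by default (downstream tools
consume physical scale) and a voxel-unit option; NTSYS export is pinned to
one rectangular-matrix dialect (`1 <nspec> <3·nlm> 0` header, label line
plus one flattened coordinate row per specimen). Several NTSYS variants
exist in the wild; pinning one, shipping its reader, and testing the round
trip bit-exactly beats guessing at all of them. TPS and NTSYS exports of
the same data decode to identical matrices.

## The precision statistic

`precision_stats` quantifies digitization repeatability: for each landmark,
the coordinate-wise (marginal) median across repeated digitizations is the
reference position, and each repeat's Euclidean distance to it, in voxel
units, is pooled by Bookstein landmark type (1: tissue juxtapositions,
2: curvature maxima, 3: extremal points). The marginal median is the
simplest reading of "the median landmark position"; the geometric (spatial)
median is a possible variant and would differ only at the second decimal
for roughly isotropic scatter. The statistic is invariant to repeat order
and to joint rigid translation.

Calibration: if repeats scatter isotropically with per-coordinate s.d. σ
voxels, the radial distance has median `σ·sqrt(qchisq(0.5, 3)) ≈ 1.538σ`.
A simulated session of 10 repeats × 12 landmarks with per-type σ of
0.5/1/2 voxels recovers type-ordered medians within 25% of that closed
form. With 40 distances per type the median estimator itself has a few
percent of Monte-Carlo noise, so the 25% band is occasionally grazed at
unlucky seeds — that is estimator variance at this study size, not bias.

## What the phantoms emulate — and what they do not

The phantom module generates volumes with analytically known geometry:
a solid sphere, a hollow shell (bone around tissue), nested shells
(multilayered structures such as fish skulls, where inner surfaces hide
behind outer ones), and a mirror-symmetric blob pair (bilateral anatomy
with exact left/right landmark pairs and a known symmetry plane), plus
seeded additive Gaussian noise (e.g. specimens fixed in unbuffered
formalin). Default intensities are background 0, soft tissue 40, bone 100
— ordered as stored CT values are.

Rasterization is hard voxel-center classification by default, so
brute-force counting oracles are exact; an anti-aliased mode with a smooth
one-voxel partial-volume edge exists because hard classification produces
staircase surface gradients (tens of degrees off the analytic normal),
while real CT data — and the anti-aliased phantom — give gradients their
analytic direction. Tests that probe gradient *direction* use the
anti-aliased mode; everything else uses the default.

What passing tests on phantoms do **not** show: real micro-CT brings beam
hardening, reconstruction artifacts, intensity inhomogeneity along a
surface, and anatomical ambiguity about where a landmark *is*. The phantom
results validate the geometry and numerics of the pipeline, not the
biological repeatability of any particular landmark set.

## Problem sizes and determinism

The test and acceptance batteries run on 32³–64³ volumes, 65×65-pixel
renders, 100-ray picking batteries, 1000 random geometry configurations and
10 × 12 precision simulations — sizes chosen so the full suite completes in
seconds while every check still operates above the resolution of its
tolerance. All randomness is seeded; phantoms with the same spec and seed
are bit-identical, picking the same pixel twice gives the identical cursor
position, and replaying a session script reproduces its exports
byte-for-byte.

## Known limitations

* Multi-frame/enhanced DICOM, compressed transfer syntaxes, gantry tilt
  and non-axial acquisitions are out of scope for the reader.
* The renderer is a reference implementation: orthographic only, no
  specular or shadow model, no acceleration structure, not real-time.
* Oblique (non-axis-aligned) reformatted slicing is not provided; the
  rotated-view geometry lives in the renderer and picking only.
* The symmetry plane comes from exactly three user-chosen landmarks; a
  least-squares plane over many pairs is deliberately not estimated.
* No statistical shape analysis (Procrustes, PCA, CVA) — exports feed the
  established morphometrics packages instead.
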