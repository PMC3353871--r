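# voxmark

Headless, scriptable digitization of 3D landmarks on volumetric (micro-CT)
image data, for geometric morphometrics.

Shape analysis of skulls and other 3D structures starts with landmark
coordinates, and the hardest landmarks to digitize reproducibly are
extremal ("type 3") points — *the anterior-most point of X*, *the tip of
Y* — which are only defined relative to a viewing geometry. voxmark
re-implements the core of an interactive landmarking workstation as an R
package: every mouse action becomes a function call or a line in a
replayable session script, so a digitization session is a reproducible
artifact.

What it does:

* **Volume I/O** — loads stacks of single-frame DICOM slices (or any
  subset) into a voxel volume with physical spacing; attribute-based slice
  ordering; block-average down-sampling (e.g. 658×658×1000 → 329×329×500
  at factor 2); a lossless binary fixture format.
* **Volume rendering** — a reference orthographic ray caster: piecewise
  linear intensity→opacity transfer function, gradient-driven reflectivity
  `clamp(g·|∇I|/max|∇I|)`, ambient + Lambertian shading under multiple
  coloured directional lights, front-to-back over-compositing
  `C += (1−A)αc, A += (1−A)α`, PNG output, text preset files.
* **Synchronized cursor & slices** — one 3D cursor per session, shared by
  all operations; three orthogonal, trilinearly interpolated cross-sections
  through it; sub-voxel cursor moves.
* **Threshold picking** — a screen pixel defines one world ray; the cursor
  lands on the first structure along it whose interpolated intensity
  exceeds a user threshold (strict `>`), bisection-refined to 10⁻³ voxel.
  Through air and soft tissue, onto the first bone-like surface.
* **Symmetry geometry** — plane from three landmarks, axis from two;
  reflection `p' = p − 2(n·p − d)n` to jump the cursor to a bilateral
  partner; view rotation so the plane normal is the viewing direction and
  the axis lies along screen x.
* **Morphometrics formats** — TPS (`LM3=` 3D dialect) and NTSYS
  rectangular-matrix export with bundled readers; landmark definition and
  symmetry-map text files; a repeat-to-median precision statistic grouped
  by Bookstein landmark type.
* **Phantoms** — synthetic skull-like volumes (spheres, nested shells,
  mirror-symmetric blob pairs, seeded noise) with analytically known
  landmarks, so the whole pipeline is testable without any scan data.

## Worked example

Digitize the two blob tips of a mirror-symmetric phantom: pick the left tip
on the rendered view's ray, mark it, reflect the cursor through the
symmetry plane, mark the partner, export TPS.

```r
library(voxmark)

spec <- phantom_spec("mirror_blobs", dims = c(48, 32, 32),
                     radius = 7, blob_offset = 12)
ph <- phantom_generate(spec)

s <- new_session()
session_set_volume(s, ph$volume)       # cursor auto-centers, slices ready
s$threshold <- 60                      # phantom bone = 100, background = 0
s$landmarks <- new_landmark_set(
  landmark_defs(1:2, c("tip of left process", "tip of right process")),
  specimen_id = "demo_skull")

pl <- plane_from_points(ph$plane_points[1, ], ph$plane_points[2, ],
                        ph$plane_points[3, ])
s$view <- rotate_to_plane(s$view, pl)  # look along the symmetry-plane normal
pick(s, c(32, 32))                     # center pixel of the 65x65 view
s$cursor$position
#> [1]  4.600586 15.500000 15.500000

s$landmarks <- mark_point(s$landmarks, 1, s$cursor)
s$cursor <- set_cursor(s$volume, s$cursor, reflect_point(pl, s$cursor$position))
s$landmarks <- mark_point(s$landmarks, 2, s$cursor)
export_tps(s$landmarks, "demo.tps")
```

`demo.tps` then contains

```
LM3=2
4.600586 15.500000 15.500000
42.399414 15.500000 15.500000
ID=demo_skull
```

The analytic tips are at x = 4.5 and x = 42.5 (y = z = 15.5): both marks
land within ~0.1 voxel, and the reflected mark is the exact mirror of the
picked one. The same workflow runs as a text script via `run_script()` —
see `?run_script` for the command language — or from a shell via
`inst/cli/voxmark.R`. Example landmark/symmetry/preset files are under
`inst/extdata/`.

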