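Package: voxmark
Title: Headless Digitization of 3D Landmarks on Volumetric Micro-CT Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scriptable toolkit for precise digitization of 3D landmarks on
    volumetric (micro-CT) image data. Loads stacks of single-frame DICOM
    slices into a voxel volume, down-samples by block averaging, renders the
    volume by orthographic ray casting with an intensity-to-opacity transfer
    function and gradient-driven Lambertian shading, maintains a single
    synchronized 3D cursor with orthogonal cross-sections, places the cursor
    on the first supra-threshold structure along a screen ray, supports
    bilateral-symmetry geometry (plane from three landmarks, axis from two
    points, reflection, view alignment), and exports landmark coordinates in
    TPS and NTSYS formats for downstream geometric morphometrics. Includes a
    synthetic skull-like phantom generator with analytically known landmarks
    so every component is testable without external data, and a scripted
    session runner replacing interactive use.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
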