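#' Specify a synthetic micro-CT-like phantom
#'
#' Phantoms emulate skull-like CT volumes: a bright shell (bone) around
#' darker interior (soft tissue/air), optionally nested shells (multilayered
#' structures such as fish skulls) or a mirror-symmetric pair of blobs
#' (bilateral structures), with optional additive Gaussian noise (e.g.
#' specimens fixed in unbuffered formalin). Geometry is analytic, so every
#' extremal landmark is known exactly.
#'
#' @param kind one of `"solid_sphere"`, `"spherical_shell"`, `"two_shell"`,
#'   `"mirror_blobs"`.
#' @param dims grid dims `(nx, ny, nz)`.
#' @param spacing voxel spacing (world units per voxel).
#' @param origin world position of voxel (0,0,0).
#' @param center world center of the structure; default the grid center
#'   (required for the exact symmetry invariants).
#' @param radius outer radius (world units) of the sphere / outer shell /
#'   each blob.
#' @param shell_thickness radial thickness of shells.
#' @param inner_radius outer radius of the inner shell (`two_shell` only).
#' @param blob_offset distance of each blob center from the symmetry plane
#'   along x (`mirror_blobs` only).
#' @param intensities named numeric `(background, soft, bone)`,
#'   strictly increasing.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise; 0 gives the deterministic phantom bit-exactly.
#' @param seed RNG seed for the noise (same seed, same volume).
#' @param antialias rasterize with a smooth one-voxel partial-volume edge
#'   instead of the default hard voxel-center classification. The default
#'   (FALSE) keeps brute-force voxel-count oracles exact; the anti-aliased
#'   mode gives surface gradients their analytic direction for renderer and
#'   shading tests.
#' @return a `phantom_spec` list, validated.
#' @export
phantom_spec <- function(kind = c("solid_sphere", "spherical_shell", "two_shell",
                                  "mirror_blobs"),
                         dims = c(64, 64, 64), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), center = NULL,
                         radius = NULL, shell_thickness = NULL,
                         inner_radius = NULL, blob_offset = NULL,
                         intensities = c(background = 0, soft = 40, bone = 100),
                         noise_sigma = 0, seed = 1L, antialias = FALSE) {
  kind <- match.arg(kind)
  dims <- as.integer(dims); spacing <- as.numeric(spacing)
  if (is.null(center)) center <- origin + (dims - 1) / 2 * spacing
  ext <- (dims - 1) / 2 * spacing  # half-extent of the voxel-center grid
  radius <- radius %||% if (kind == "mirror_blobs") {
    0.45 * min(ext[1], 2 * ext[2], 2 * ext[3])
  } else {
    0.8 * min(ext)
  }
  shell_thickness <- shell_thickness %||% max(2 * min(spacing), radius / 6)
  inner_radius <- inner_radius %||% (radius / 2)
  blob_offset <- blob_offset %||% (0.45 * ext[1])
  if (length(intensities) != 3 || any(diff(intensities) <= 0)) {
    stop("intensities must be 3 increasing values (background < soft < bone)",
         call. = FALSE)
  }
  names(intensities) <- c("background", "soft", "bone")
  fits <- switch(kind,
    mirror_blobs = all(blob_offset + radius <= ext[1] + 1e-9) &&
      radius <= min(ext[2:3]) + 1e-9,
    radius <= min(ext) + 1e-9)
  if (!fits) stop("phantom geometry exceeds the volume bounds", call. = FALSE)
  if (kind == "two_shell" && inner_radius >= radius - shell_thickness) {
    stop("inner shell must fit strictly inside the outer shell", call. = FALSE)
  }
  structure(list(kind = kind, dims = dims, spacing = spacing, origin = origin,
                 center = as.numeric(center), radius = radius,
                 shell_thickness = shell_thickness, inner_radius = inner_radius,
                 blob_offset = blob_offset, intensities = intensities,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 antialias = isTRUE(antialias)),
            class = "phantom_spec")
}

#' Generate a phantom volume with analytically known landmarks
#'
#' Solids are rasterized at voxel centers without anti-aliasing, so
#' brute-force voxel-count oracles are exact. Ground-truth landmarks are the
#' axis extrema (±x, ±y, ±z) of each surface; `mirror_blobs` additionally
#' reports exact left/right landmark pairs and three points spanning the
#' symmetry plane.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [new_volume()]), `landmarks` (named n x 3
#'   matrix of world points), and for `mirror_blobs` also `pairs` (data.frame
#'   of left/right landmark names) and `plane_points` (3 x 3 matrix on the
#'   symmetry plane).
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims; sp <- spec$spacing; o <- spec$origin; ctr <- spec$center
  ints <- spec$intensities
  x <- o[1] + (seq_len(d[1]) - 1) * sp[1]
  y <- o[2] + (seq_len(d[2]) - 1) * sp[2]
  z <- o[3] + (seq_len(d[3]) - 1) * sp[3]
  dist2 <- function(cx, cy, cz) {
    outer(outer((x - cx)^2, (y - cy)^2, "+"), (z - cz)^2, "+")
  }
  R <- spec$radius; t <- spec$shell_thickness
  ext_names <- function(prefix, c0, r) {
    pts <- rbind(c0 - c(r, 0, 0), c0 + c(r, 0, 0),
                 c0 - c(0, r, 0), c0 + c(0, r, 0),
                 c0 - c(0, 0, r), c0 + c(0, 0, r))
    rownames(pts) <- paste0(prefix, c("_xmin", "_xmax", "_ymin", "_ymax",
                                      "_zmin", "_zmax"))
    pts
  }
  # sphere coverage at each voxel center: hard classification by default,
  # or a smooth one-voxel partial-volume edge in anti-aliased mode
  w_edge <- max(sp)
  cov <- function(r2, R) {
    if (spec$antialias) {
      clamp((R - sqrt(r2)) / w_edge + 0.5, 0, 1)
    } else {
      as.numeric(r2 <= R^2)
    }
  }
  bg <- ints["background"]; soft <- ints["soft"]; bone <- ints["bone"]
  pairs <- NULL; plane_points <- NULL
  if (spec$kind == "solid_sphere") {
    r2 <- dist2(ctr[1], ctr[2], ctr[3])
    a <- array(bg + (bone - bg) * cov(r2, R), dim = d)
    lm <- ext_names("surface", ctr, R)
  } else if (spec$kind == "spherical_shell") {
    r2 <- dist2(ctr[1], ctr[2], ctr[3])
    a <- array(bg + (bone - bg) * cov(r2, R) - (bone - soft) * cov(r2, R - t),
               dim = d)
    lm <- rbind(ext_names("outer", ctr, R), ext_names("inner", ctr, R - t))
  } else if (spec$kind == "two_shell") {
    r2 <- dist2(ctr[1], ctr[2], ctr[3])
    Ri <- spec$inner_radius
    a <- array(bg + (bone - bg) * cov(r2, R) -        # outer shell edge
                 (bone - soft) * cov(r2, R - t) +     # gap below the shell
                 (bone - soft) * cov(r2, Ri) -        # inner shell edge
                 (bone - soft) * cov(r2, Ri - t),     # soft core
               dim = d)
    lm <- rbind(ext_names("outer", ctr, R), ext_names("inner", ctr, Ri))
  } else {  # mirror_blobs
    off <- spec$blob_offset
    cl <- ctr - c(off, 0, 0); cr <- ctr + c(off, 0, 0)
    a <- array(bg + (bone - bg) *
                 pmin(1, cov(dist2(cl[1], cl[2], cl[3]), R) +
                        cov(dist2(cr[1], cr[2], cr[3]), R)),
               dim = d)
    lm <- rbind(ext_names("left", cl, R), ext_names("right", cr, R))
    lut <- c(xmin = "xmax", xmax = "xmin", ymin = "ymin", ymax = "ymax",
             zmin = "zmin", zmax = "zmax")
    pairs <- data.frame(
      left = paste0("left_", names(lut)),
      right = paste0("right_", unname(lut)),
      stringsAsFactors = FALSE
    )
    plane_points <- rbind(ctr, ctr + c(0, 1, 0) * max(sp), ctr + c(0, 0, 1) * max(sp))
    rownames(plane_points) <- c("PL1", "PL2", "PL3")
  }
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d))
    a <- a + noise
  }
  out <- list(volume = new_volume(a, spacing = sp, origin = o),
              landmarks = lm, spec = spec)
  if (!is.null(pairs)) {
    out$pairs <- pairs
    out$plane_points <- plane_points
  }
  out
}

#' Write a phantom's ground-truth landmarks as a plain-text table
#'
#' One line per landmark: `name x y z` (world units), `#` comments allowed.
#'
#' @param ph result of [phantom_generate()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ph, path) {
  lm <- ph$landmarks
  lines <- c("# phantom ground-truth landmarks: name x y z",
             sprintf("%s %.9g %.9g %.9g", rownames(lm), lm[, 1], lm[, 2], lm[, 3]))
  writeLines(lines, path)
  invisible(path)
}
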