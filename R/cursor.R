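#' The synchronized 3D cursor
#'
#' All slicing, picking and landmark marking flow through a single cursor:
#' one continuous world position plus its nearest voxel index. Positions are
#' clamped to the voxel-center bounds of the volume on every move, and
#' sub-voxel positions are allowed (slices interpolate), which is what makes
#' extreme-point refinement finer than the grid possible.
#'
#' @name cursor
NULL

new_cursor <- function(v, position) {
  position <- clamp(as.numeric(position), vol_bounds(v)[1, ], vol_bounds(v)[2, ])
  structure(list(position = position,
                 voxel_index = as.integer(round(world_to_index(v, position)))),
            class = "cursor3d")
}

#' Initialize the cursor at the volume center
#'
#' @param v a volume.
#' @return a `cursor3d` at the center of the voxel-center grid, i.e. voxel
#'   index `(nx-1)/2, (ny-1)/2, (nz-1)/2` in world units.
#' @export
init_cursor <- function(v) {
  stopifnot(is_volume(v))
  new_cursor(v, v$origin + (v$dims - 1) / 2 * v$spacing)
}

#' Move the cursor along a volume axis
#'
#' @param v the volume the cursor lives in (for spacing and bounds).
#' @param cursor a `cursor3d`.
#' @param axis `"x"`, `"y"` or `"z"` (volume axes).
#' @param delta_voxels signed move in voxel units (sub-voxel allowed); the
#'   world shift is `delta_voxels * spacing[axis]`, clamped to bounds.
#' @return the moved `cursor3d`.
#' @export
move_cursor <- function(v, cursor, axis = c("x", "y", "z"), delta_voxels) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  p <- cursor$position
  p[a] <- p[a] + delta_voxels * v$spacing[a]
  new_cursor(v, p)
}

#' Place the cursor at a world position
#'
#' @param v a volume.
#' @param cursor a `cursor3d` (ignored except for class symmetry).
#' @param position target world position, clamped to bounds.
#' @return the repositioned `cursor3d`.
#' @export
set_cursor <- function(v, cursor, position) new_cursor(v, position)

#' Extract the three orthogonal cross-sections through the cursor
#'
#' Slices are aligned with the volume's major axes (not any rotated view):
#' the yz-plane at the cursor's x, the xz-plane at its y, and the xy-plane
#' at its z. Planes at non-integer cursor coordinates are sampled by
#' trilinear interpolation; at integer voxel coordinates the interpolation
#' degenerates to the raw grid plane.
#'
#' @param v a volume.
#' @param cursor a `cursor3d` inside `v`.
#' @return list of three matrices `yz` (ny x nz), `xz` (nx x nz),
#'   `xy` (nx x ny), plus `cursor_in_plane`, the cursor's continuous
#'   in-plane voxel coordinates for each slice (for cross-hair overlay).
#' @export
extract_slices <- function(v, cursor) {
  stopifnot(is_volume(v), inherits(cursor, "cursor3d"))
  d <- v$dims
  u <- world_to_index(v, cursor$position)
  ax_w <- function(a) v$origin[a] + (seq_len(d[a]) - 1) * v$spacing[a]
  xs <- ax_w(1); ys <- ax_w(2); zs <- ax_w(3)
  p <- cursor$position
  slice <- function(grid_a, grid_b, fixed_axis) {
    g <- expand.grid(a = grid_a, b = grid_b)
    pts <- switch(fixed_axis,
                  x = cbind(p[1], g$a, g$b),
                  y = cbind(g$a, p[2], g$b),
                  z = cbind(g$a, g$b, p[3]))
    matrix(vol_interp(v, pts), nrow = length(grid_a))
  }
  list(
    yz = slice(ys, zs, "x"),
    xz = slice(xs, zs, "y"),
    xy = slice(xs, ys, "z"),
    cursor_in_plane = list(yz = u[2:3], xz = u[c(1, 3)], xy = u[1:2])
  )
}

#' Write the three cursor slices as PNG files
#'
#' @param v a volume.
#' @param cursor a `cursor3d`.
#' @param prefix output path prefix; writes `<prefix>_yz.png`,
#'   `<prefix>_xz.png`, `<prefix>_xy.png`.
#' @param crosshair burn the cursor cross-hair into the images?
#' @return the three paths, invisibly.
#' @export
save_slices_png <- function(v, cursor, prefix, crosshair = TRUE) {
  sl <- extract_slices(v, cursor)
  paths <- character(3)
  for (i in 1:3) {
    nm <- c("yz", "xz", "xy")[i]
    m <- sl[[nm]]
    rngv <- range(m)
    m <- if (diff(rngv) > 0) (m - rngv[1]) / diff(rngv) else m * 0
    if (crosshair) {
      cp <- round(sl$cursor_in_plane[[nm]]) + 1
      cp <- pmin(pmax(cp, 1), dim(m))
      m[cp[1], ] <- 1
      m[, cp[2]] <- 1
    }
    paths[i] <- file.path(paste0(prefix, "_", nm, ".png"))
    # image convention: first slice axis horizontal, second vertical (top row last)
    png::writePNG(clamp(t(m)[rev(seq_len(ncol(m))), , drop = FALSE], 0, 1), paths[i])
  }
  invisible(paths)
}
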