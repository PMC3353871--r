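# Bilateral-symmetry geometry aids: a plane defined by three landmarks
# (e.g. the sagittal/median plane), an axis by two end points, reflection of
# points through the plane, and view alignment so the plane normal becomes
# the viewing direction with the axis along screen x. These are the tools
# that make type-3 (extremal) landmarks reproducible.

#' Plane through three landmarks
#'
#' The normal follows the cross-product convention from the given point
#' order, `unit((p2 - p1) x (p3 - p1))`; reflection is sign-invariant, and
#' view alignment offers `flip_normal` for the other side.
#'
#' @param p1,p2,p3 world points (length 3), non-collinear.
#' @return a `plane_spec`: `p1, p2, p3`, unit `normal`, and `offset` (the
#'   signed distance of the plane from the world origin, `normal . p`).
#' @export
plane_from_points <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  scale <- max(vnorm(p2 - p1), vnorm(p3 - p1), vnorm(p3 - p2))
  n0 <- cross3(p2 - p1, p3 - p1)
  if (scale == 0 || vnorm(n0) / 2 <= 1e-9 * scale^2) {
    stop("plane points are collinear or coincident (p1, p2, p3 span no triangle)",
         call. = FALSE)
  }
  normal <- unitv(n0)
  structure(list(p1 = p1, p2 = p2, p3 = p3, normal = normal,
                 offset = sum(normal * p1)),
            class = "plane_spec")
}

#' Axis through two end points
#'
#' @param a1,a2 distinct world points.
#' @return an `axis_spec`: `a1`, `a2`, unit `direction = (a2 - a1)/|a2 - a1|`.
#' @export
axis_from_points <- function(a1, a2) {
  a1 <- as.numeric(a1); a2 <- as.numeric(a2)
  if (vnorm(a2 - a1) < 1e-12) stop("axis end points coincide", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, direction = unitv(a2 - a1)),
            class = "axis_spec")
}

#' Reflect a point (or points) through a plane
#'
#' `p' = p - 2 (normal . p - offset) normal`: an involutive isometry. Used
#' to carry the cursor from a marked landmark to its bilateral partner.
#'
#' @param plane a [plane_from_points()] result.
#' @param p world point (length 3) or n x 3 matrix.
#' @return reflected point(s), same shape as `p`.
#' @export
reflect_point <- function(plane, p) {
  stopifnot(inherits(plane, "plane_spec"))
  n <- plane$normal
  if (is.matrix(p)) {
    s <- as.numeric(p %*% n) - plane$offset
    p - 2 * s %o% n
  } else {
    p - 2 * (sum(p * n) - plane$offset) * n
  }
}

#' Align the viewing direction with a plane normal
#'
#' Sets `forward` to the plane normal and completes `{right, up}` by
#' projecting the previous up-vector into the new view plane (minimal
#' rotation), falling back to world z then y when degenerate. The view
#' center is preserved. Applying it twice changes nothing.
#'
#' @param view a [view_state()].
#' @param plane a `plane_spec`.
#' @param flip_normal look from the other side of the plane?
#' @return the rotated `view_state`.
#' @export
rotate_to_plane <- function(view, plane, flip_normal = FALSE) {
  stopifnot(inherits(view, "view_state"), inherits(plane, "plane_spec"))
  f <- if (flip_normal) -plane$normal else plane$normal
  view_state(center = view$center, forward = f, up = view$up,
             image_size = view$image_size, pixel_pitch = view$pixel_pitch)
}

#' Align the view with a plane normal and an in-plane axis
#'
#' `forward` becomes the plane normal; screen x (`right`) becomes the axis
#' direction projected into the view plane; `up = forward x right` completes
#' the right-handed frame. After the call the axis has no screen-y
#' component.
#'
#' @param view a [view_state()].
#' @param plane a `plane_spec`.
#' @param axis an [axis_from_points()] result, not parallel to the normal.
#' @param flip_normal look from the other side of the plane?
#' @return the rotated `view_state`.
#' @export
rotate_to_axis <- function(view, plane, axis, flip_normal = FALSE) {
  stopifnot(inherits(view, "view_state"), inherits(plane, "plane_spec"),
            inherits(axis, "axis_spec"))
  f <- if (flip_normal) -plane$normal else plane$normal
  r0 <- axis$direction - sum(axis$direction * f) * f
  if (vnorm(r0) < 1e-6) {
    stop("axis is (near-)parallel to the plane normal; cannot define screen x",
         call. = FALSE)
  }
  r <- unitv(r0)
  u <- cross3(f, r)  # right x up = forward
  out <- view
  out$forward <- f
  out$right <- r
  out$up <- u
  out
}
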