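# Screen-ray picking: a pixel under an orthographic view defines one world
# ray; the cursor is placed on the first structure along it whose
# (trilinearly interpolated) intensity exceeds a user threshold. This is
# the headless analogue of clicking on the rendered image in pick mode.

#' World ray beneath an image pixel
#'
#' Orthographic: the ray base lies on the image plane at the pixel center
#' and the direction is the viewing direction. Pixel centers are symmetric
#' about the view center (`col - (w-1)/2` columns across), so the center
#' pixel of an odd-sized image maps exactly to `view$center`.
#'
#' @param view a [view_state()].
#' @param pixel `(col, row)`, 0-based, row 0 at the top.
#' @return a `ray`: list with `base` (world point) and `direction`
#'   (unit vector, `= view$forward`).
#' @export
screen_ray <- function(view, pixel) {
  stopifnot(inherits(view, "view_state"))
  col <- pixel[1]; row <- pixel[2]
  w <- view$image_size[1]; h <- view$image_size[2]
  if (col < 0 || col > w - 1 || row < 0 || row > h - 1) {
    stop(sprintf("pixel (%g, %g) outside image %d x %d", col, row, w, h),
         call. = FALSE)
  }
  base <- view$center +
    (col - (w - 1) / 2) * view$pixel_pitch * view$right +
    ((h - 1) / 2 - row) * view$pixel_pitch * view$up
  structure(list(base = base, direction = view$forward), class = "ray")
}

#' First supra-threshold point along a ray
#'
#' Marches the ray from volume entry to exit at the rendering step size,
#' testing the trilinearly interpolated intensity against
#' `intensity > threshold` (strict). The first bracketing pair of samples is
#' refined by bisection to sub-step accuracy, returning the near end of the
#' final bracket (so the returned point itself satisfies the threshold).
#' When the entry sample already exceeds the threshold the entry point is
#' returned, i.e. a threshold below the global minimum yields the ray's
#' entry into the volume.
#'
#' @param v a volume.
#' @param ray a [screen_ray()] result (or list with `base`, `direction`).
#' @param threshold intensity threshold (finite). No scanner-independent
#'   default exists — bone intensity depends on the scan — so it must be
#'   given explicitly.
#' @param step march step in world units, default `0.5 * min(spacing)`.
#' @param refine_tol bisection tolerance in voxel units along the ray.
#' @return the hit as a world point (length 3), or `NULL` when the ray
#'   misses the volume's bounding box or never exceeds the threshold (the
#'   two cases are distinguished in the session log by [pick()]).
#' @export
first_hit <- function(v, ray, threshold, step = NULL, refine_tol = 1e-3) {
  first_hit_detail(v, ray, threshold, step, refine_tol)$point
}

# as first_hit, but also reports why there was no hit:
# list(point = vec3 | NULL, reason = "hit" | "miss" | "below_threshold")
first_hit_detail <- function(v, ray, threshold, step = NULL, refine_tol = 1e-3) {
  stopifnot(is_volume(v), is.finite(threshold))
  if (is.null(step)) step <- 0.5 * min(v$spacing)
  dir <- unitv(ray$direction)
  rng <- ray_box_range(v, matrix(ray$base, 1, 3), dir)
  t0 <- rng$t0; t1 <- rng$t1
  if (!(t0 <= t1) || !is.finite(t0)) {
    return(list(point = NULL, reason = "miss"))
  }
  ts <- seq(t0, t1, by = step)
  if (ts[length(ts)] < t1) ts <- c(ts, t1)
  pts <- matrix(ray$base, length(ts), 3, byrow = TRUE) + ts %o% dir
  vals <- vol_interp(v, pts)
  hit <- which(vals > threshold)
  if (length(hit) == 0) {
    return(list(point = NULL, reason = "below_threshold"))
  }
  i <- hit[1]
  if (i == 1) return(list(point = as.numeric(pts[1, ]), reason = "hit"))
  a <- ts[i - 1]; b <- ts[i]
  tol <- refine_tol * min(v$spacing)
  while (b - a > tol) {
    m <- (a + b) / 2
    if (vol_interp(v, ray$base + m * dir) > threshold) b <- m else a <- m
  }
  list(point = as.numeric(ray$base + b * dir), reason = "hit")
}

#' Pick: move the session cursor to the first structure under a pixel
#'
#' Composes [screen_ray()] and [first_hit()] using the session's configured
#' view and threshold, moves the session's (single) cursor to the hit and
#' regenerates the orthogonal slices. A miss leaves the cursor unchanged
#' and emits a warning.
#'
#' @param session a [new_session()] with a volume, view and threshold set.
#' @param pixel `(col, row)`, 0-based.
#' @return the session's `cursor3d`, invisibly.
#' @export
pick <- function(session, pixel) {
  stopifnot(inherits(session, "landmark_session"))
  if (is.null(session$volume)) stop("no volume loaded", call. = FALSE)
  if (is.null(session$view)) stop("no view configured", call. = FALSE)
  if (is.null(session$threshold)) {
    stop("no picking threshold configured (set one explicitly; it is scan-dependent)",
         call. = FALSE)
  }
  ray <- screen_ray(session$view, pixel)
  res <- first_hit_detail(session$volume, ray, session$threshold)
  hit <- res$point
  if (is.null(hit)) {
    warning("pick at pixel (", pixel[1], ", ", pixel[2], ") found no structure (",
            res$reason, "); cursor unchanged")
  } else {
    session$cursor <- set_cursor(session$volume, session$cursor, hit)
    session$slices <- extract_slices(session$volume, session$cursor)
  }
  session_log(session, sprintf("pick %g %g -> %s", pixel[1], pixel[2],
                               if (is.null(hit)) res$reason else
                                 paste(sprintf("%.6f", hit), collapse = " ")))
  invisible(session$cursor)
}
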