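#' Orthographic camera frame
#'
#' A view is a right-handed orthonormal world frame `{right, up, forward}`
#' (`forward` is the viewing direction, i.e. rays travel along `+forward`),
#' a world point the camera looks at, and an image-plane geometry. The
#' projection is orthographic: each pixel defines exactly one world ray,
#' which is what makes screen picking well defined.
#'
#' @param center world point the camera looks at (image-plane center).
#' @param forward viewing direction (normalized internally).
#' @param up up-vector hint; its component along `forward` is removed. Falls
#'   back to world z, then world y, when (near-)parallel to `forward`.
#' @param image_size `(w, h)` in pixels.
#' @param pixel_pitch world units per pixel.
#' @return a `view_state` with fields `right`, `up`, `forward`, `center`,
#'   `image_size`, `pixel_pitch`.
#' @export
view_state <- function(center, forward = c(0, 0, 1), up = c(0, 1, 0),
                       image_size = c(65, 65), pixel_pitch = 1) {
  f <- unitv(as.numeric(forward))
  u0 <- as.numeric(up) - sum(as.numeric(up) * f) * f
  if (vnorm(u0) < 1e-9) {
    for (cand in list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))) {
      u0 <- cand - sum(cand * f) * f
      if (vnorm(u0) >= 1e-9) break
    }
  }
  u <- unitv(u0)
  r <- cross3(u, f)  # right x up = forward (right-handed)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 1)) {
    stop("image_size must be two positive integers (w, h)", call. = FALSE)
  }
  if (!isTRUE(pixel_pitch > 0)) stop("pixel_pitch must be > 0", call. = FALSE)
  structure(list(right = r, up = u, forward = f, center = as.numeric(center),
                 image_size = image_size, pixel_pitch = as.numeric(pixel_pitch)),
            class = "view_state")
}

# frame orthonormality / handedness checks, used by tests and geometry ops
view_frame_error <- function(view) {
  M <- rbind(view$right, view$up, view$forward)
  max(abs(M %*% t(M) - diag(3)),
      abs(cross3(view$right, view$up) - view$forward))
}

#' A view sized to frame a whole volume
#'
#' Convenience constructor: looks at the volume center with a square image
#' plane large enough to contain the volume's bounding sphere.
#'
#' @param v a volume.
#' @param forward,up as in [view_state()].
#' @param image_px image width = height in pixels (odd values keep the
#'   center pixel exactly on the view center).
#' @return a `view_state`.
#' @export
view_for_volume <- function(v, forward = c(0, 0, 1), up = c(0, 1, 0),
                            image_px = 65) {
  b <- vol_bounds(v)
  ctr <- colMeans(b)
  half_diag <- vnorm((b[2, ] - b[1, ]) / 2)
  pitch <- 2 * half_diag / (image_px - 1)
  view_state(center = ctr, forward = forward, up = up,
             image_size = c(image_px, image_px), pixel_pitch = pitch)
}
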