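# Volume rendering: intensity -> opacity transfer function, gradient-driven
# reflectivity, multi-light Lambertian shading and front-to-back compositing
# along orthographic rays. The brute-force ray caster below is the reference
# renderer; every other component (picking, geometry views) shares its
# sampling conventions.

#' Intensity-to-opacity transfer function
#'
#' A piecewise-linear opacity ramp: 0 below `low_intensity`, `max_opacity`
#' at/above `high_intensity`, linear in between. `mode = "surface"` is the
#' conventional steep ramp isolating one intensity band (e.g. bone);
#' `mode = "translucent"` is a low `max_opacity` over a broad band so all
#' surfaces render simultaneously. The mode tag is descriptive; the ramp
#' parameters carry the behaviour.
#'
#' @param low_intensity,high_intensity ramp ends, `low <= high`.
#' @param max_opacity plateau opacity in `[0, 1]`.
#' @param reflectivity_gain scalar >= 0 multiplying the normalized gradient
#'   magnitude into surface reflectivity (clamped to `[0, 1]`).
#' @param mode `"surface"` or `"translucent"`.
#' @return a `transfer_function`.
#' @export
transfer_function <- function(low_intensity, high_intensity, max_opacity = 1,
                              reflectivity_gain = 1,
                              mode = c("surface", "translucent")) {
  mode <- match.arg(mode)
  if (!(low_intensity <= high_intensity)) {
    stop("low_intensity must be <= high_intensity", call. = FALSE)
  }
  if (max_opacity < 0 || max_opacity > 1) stop("max_opacity must be in [0,1]", call. = FALSE)
  if (reflectivity_gain < 0) stop("reflectivity_gain must be >= 0", call. = FALSE)
  structure(list(low_intensity = low_intensity, high_intensity = high_intensity,
                 max_opacity = max_opacity, reflectivity_gain = reflectivity_gain,
                 mode = mode),
            class = "transfer_function")
}

#' Evaluate a transfer function's opacity ramp
#'
#' @param tf a [transfer_function()].
#' @param intensity numeric vector of intensities.
#' @return opacities in `[0, max_opacity]`.
#' @export
tf_opacity <- function(tf, intensity) {
  lo <- tf$low_intensity; hi <- tf$high_intensity
  if (hi > lo) {
    clamp((intensity - lo) / (hi - lo), 0, 1) * tf$max_opacity
  } else {
    ifelse(intensity >= hi, tf$max_opacity, 0)
  }
}

#' Directional light set
#'
#' @param directions k x 3 matrix (or length-3 vector) of light directions,
#'   pointing from the surface toward the light; normalized internally.
#' @param intensities k light intensities >= 0.
#' @param colours k x 3 matrix of RGB in `[0,1]` (default white).
#' @param ambient ambient intensity >= 0.
#' @param background background RGB filled in behind residual transparency.
#' @return a `light_set`.
#' @export
light_set <- function(directions = c(0, 0, -1), intensities = 1,
                      colours = NULL, ambient = 0.1,
                      background = c(0, 0, 0)) {
  if (!is.matrix(directions)) directions <- matrix(directions, ncol = 3, byrow = TRUE)
  k <- nrow(directions)
  directions <- t(apply(directions, 1, unitv))
  if (k == 1) dim(directions) <- c(1, 3)
  intensities <- rep_len(as.numeric(intensities), k)
  if (any(intensities < 0)) stop("light intensities must be >= 0", call. = FALSE)
  if (is.null(colours)) colours <- matrix(1, k, 3)
  if (!is.matrix(colours)) colours <- matrix(colours, ncol = 3, byrow = TRUE)
  colours <- colours[rep_len(seq_len(nrow(colours)), k), , drop = FALSE]
  if (ambient < 0) stop("ambient must be >= 0", call. = FALSE)
  if (ambient == 0 && (k == 0 || all(intensities == 0))) {
    stop("need ambient light or at least one light", call. = FALSE)
  }
  structure(list(directions = directions, intensities = intensities,
                 colours = clamp(colours, 0, 1), ambient = as.numeric(ambient),
                 background = clamp(as.numeric(background), 0, 1)),
            class = "light_set")
}

#' Lambertian shading of one surface sample
#'
#' `rgb = clamp((ambient + sum_l I_l * colour_l * reflectivity *
#' max(0, normal . direction_l)) * base_colour)`. A zero/undefined normal
#' (zero gradient) shades ambient-only.
#'
#' @param normal_dir unit surface normal (or zero vector).
#' @param reflectivity diffuse gain in `[0, 1]`.
#' @param lights a [light_set()].
#' @param base_colour RGB base colour.
#' @return RGB vector in `[0, 1]`.
#' @export
shade <- function(normal_dir, reflectivity, lights, base_colour = c(1, 1, 1)) {
  as.numeric(shade_batch(matrix(normal_dir, 1, 3), reflectivity, lights,
                         matrix(base_colour, 1, 3)))
}

# vectorized shading: normals n x 3 (zero rows allowed), refl length n,
# base n x 3 -> n x 3 RGB
shade_batch <- function(normals, refl, lights, base) {
  n <- nrow(normals)
  coef <- matrix(lights$ambient, n, 3)
  for (l in seq_len(nrow(lights$directions))) {
    ndl <- pmax(0, as.numeric(normals %*% lights$directions[l, ]))
    w <- lights$intensities[l] * refl * ndl
    coef <- coef + outer(w, lights$colours[l, ])
  }
  clamp(coef * base, 0, 1)
}

#' Front-to-back compositing of one ray's samples
#'
#' Standard over-operator: `C += (1 - A) * alpha_i * c_i`,
#' `A += (1 - A) * alpha_i`, with early termination at `A >= 0.999`.
#' Residual transparency is the caller's to fill with background.
#'
#' @param colours n x 3 matrix of sample RGB, front to back.
#' @param opacities n sample opacities in `[0, 1]`.
#' @return list with `colour` (RGB) and `alpha` (accumulated opacity).
#' @export
composite_ray <- function(colours, opacities) {
  if (!is.matrix(colours)) colours <- matrix(colours, ncol = 3, byrow = TRUE)
  stopifnot(length(opacities) == nrow(colours), all(opacities >= 0),
            all(opacities <= 1))
  C <- c(0, 0, 0); A <- 0
  for (i in seq_along(opacities)) {
    if (A >= 0.999) break
    w <- (1 - A) * opacities[i]
    C <- C + w * colours[i, ]
    A <- A + w
  }
  list(colour = C, alpha = A)
}

# entry/exit ray parameters against the voxel-center bounding box;
# bases n x 3, single direction; returns list(t0, t1) with t0 > t1 for misses
ray_box_range <- function(v, bases, dir) {
  b <- vol_bounds(v)
  n <- nrow(bases)
  t0 <- rep(-Inf, n); t1 <- rep(Inf, n)
  for (a in 1:3) {
    if (abs(dir[a]) < 1e-14) {
      miss <- bases[, a] < b[1, a] - 1e-12 | bases[, a] > b[2, a] + 1e-12
      t0[miss] <- Inf
    } else {
      ta <- (b[1, a] - bases[, a]) / dir[a]
      tb <- (b[2, a] - bases[, a]) / dir[a]
      t0 <- pmax(t0, pmin(ta, tb))
      t1 <- pmin(t1, pmax(ta, tb))
    }
  }
  list(t0 = t0, t1 = t1)
}

#' Reference volume renderer: brute-force orthographic ray casting
#'
#' For each pixel, a ray is marched through the volume at a fixed step
#' (default half the smallest voxel spacing), intensity is sampled
#' trilinearly, mapped to opacity by the transfer function, shaded with
#' gradient-driven Lambertian reflection, and composited front to back.
#' Residual transparency is blended with the light set's background colour.
#' Reflectivity is `clamp(reflectivity_gain * |grad| / max|grad|)` with the
#' maximum taken over the volume, so the transfer function is independent of
#' intensity units.
#'
#' @param v a volume.
#' @param view a [view_state()].
#' @param tf a [transfer_function()].
#' @param lights a [light_set()].
#' @param step ray sampling step in world units; default
#'   `0.5 * min(spacing)`.
#' @param base_colour foreground base RGB (tint for pseudo-colour renders).
#' @return a `rendered_image`: list with `pixels` (h x w x 3 array in
#'   `[0,1]`) and `provenance` (view/tf/lights used).
#' @export
render_raycast <- function(v, view, tf, lights, step = NULL,
                           base_colour = c(1, 1, 1)) {
  stopifnot(is_volume(v), inherits(view, "view_state"),
            inherits(tf, "transfer_function"), inherits(lights, "light_set"))
  if (is.null(step)) step <- 0.5 * min(v$spacing)
  w <- view$image_size[1]; h <- view$image_size[2]
  px <- expand.grid(col = seq_len(w) - 1, row = seq_len(h) - 1)
  xoff <- (px$col - (w - 1) / 2) * view$pixel_pitch
  yoff <- ((h - 1) / 2 - px$row) * view$pixel_pitch
  bases <- matrix(view$center, nrow(px), 3, byrow = TRUE) +
    outer(xoff, view$right) + outer(yoff, view$up)
  dir <- view$forward
  rng <- ray_box_range(v, bases, dir)
  n <- nrow(bases)
  C <- matrix(0, n, 3); A <- numeric(n)
  grids <- vol_gradient_grids(v)
  gmax <- sqrt(max(grids$gx^2 + grids$gy^2 + grids$gz^2))
  gvols <- lapply(grids, function(g) new_volume(g, spacing = v$spacing,
                                                origin = v$origin))
  span <- rng$t1 - rng$t0
  K <- if (any(span > 0)) ceiling(max(span[span > 0]) / step) else 0
  for (k in seq_len(K)) {
    tk <- rng$t0 + (k - 0.5) * step
    act <- which(tk <= rng$t1 & A < 0.999)
    if (length(act) == 0) next
    pts <- bases[act, , drop = FALSE] + tk[act] %o% dir
    val <- vol_interp(v, pts)
    alpha <- tf_opacity(tf, val)
    nz <- which(alpha > 1e-6)
    if (length(nz) == 0) next
    act <- act[nz]; pts <- pts[nz, , drop = FALSE]; alpha <- alpha[nz]
    g <- cbind(vol_interp(gvols$gx, pts), vol_interp(gvols$gy, pts),
               vol_interp(gvols$gz, pts))
    gn <- sqrt(rowSums(g^2))
    refl <- if (gmax > 0) clamp(tf$reflectivity_gain * gn / gmax, 0, 1) else rep(0, length(gn))
    normals <- matrix(0, length(gn), 3)
    ok <- gn > 1e-12
    # bright structures on dark background: outward normal = -gradient
    normals[ok, ] <- -g[ok, , drop = FALSE] / gn[ok]
    col <- shade_batch(normals, refl, lights,
                       matrix(base_colour, length(gn), 3, byrow = TRUE))
    wgt <- (1 - A[act]) * alpha
    C[act, ] <- C[act, ] + wgt * col
    A[act] <- A[act] + wgt
  }
  C <- C + (1 - A) %o% lights$background
  pixels <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) pixels[, , ch] <- t(matrix(C[, ch], nrow = w))
  pixels <- clamp(pixels, 0, 1)
  structure(list(pixels = pixels,
                 provenance = list(view = view, tf = tf, lights = lights,
                                   step = step, base_colour = base_colour)),
            class = "rendered_image")
}

#' Write a rendered image (or a grayscale slice) as PNG
#'
#' @param img a `rendered_image`, an h x w x 3 array in `[0,1]`, or a 2D
#'   intensity matrix (rescaled to `[0,1]` for display).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_png <- function(img, path) {
  if (inherits(img, "rendered_image")) img <- img$pixels
  if (is.matrix(img)) {
    rngv <- range(img)
    img <- if (diff(rngv) > 0) (img - rngv[1]) / diff(rngv) else img * 0
    img <- t(img)[rev(seq_len(ncol(img))), , drop = FALSE]
  }
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

#' Load transfer-function and light presets from a key=value text file
#'
#' Recognized keys: `low`, `high`, `max_opacity`, `reflectivity_gain`,
#' `mode`, `ambient`, `background` (r,g,b), `light` (dx,dy,dz,intensity
#' optionally r,g,b — repeatable). Lines starting with `#` are comments.
#'
#' @param path preset file.
#' @return list with `tf` ([transfer_function()]) and `lights`
#'   ([light_set()]).
#' @export
read_render_preset <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("bad preset line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  num <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  get1 <- function(k, default) if (k %in% keys) num(vals[match(k, keys)]) else default
  mode <- if ("mode" %in% keys) vals[match("mode", keys)] else "surface"
  tf <- transfer_function(get1("low", 0), get1("high", 1),
                          max_opacity = get1("max_opacity", 1),
                          reflectivity_gain = get1("reflectivity_gain", 1),
                          mode = mode)
  li <- which(keys == "light")
  if (length(li)) {
    parts <- lapply(vals[li], num)
    dirs <- t(vapply(parts, function(p) p[1:3], numeric(3)))
    ints <- vapply(parts, function(p) if (length(p) >= 4) p[4] else 1, numeric(1))
    cols <- t(vapply(parts, function(p) if (length(p) >= 7) p[5:7] else c(1, 1, 1),
                     numeric(3)))
    lights <- light_set(dirs, ints, cols, ambient = get1("ambient", 0.1),
                        background = get1("background", c(0, 0, 0)))
  } else {
    lights <- light_set(ambient = max(get1("ambient", 1), 1e-6),
                        background = get1("background", c(0, 0, 0)))
  }
  list(tf = tf, lights = lights)
}
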