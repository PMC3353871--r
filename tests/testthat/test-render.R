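test_that("opacity ramp: zero below, linear between, saturated above", {
  tf <- transfer_function(100, 200, max_opacity = 1)
  expect_equal(tf_opacity(tf, 50), 0)
  expect_equal(tf_opacity(tf, 100), 0)
  expect_equal(tf_opacity(tf, 150), 0.5)
  expect_equal(tf_opacity(tf, 250), 1)
  tf2 <- transfer_function(100, 200, max_opacity = 0.3, mode = "translucent")
  expect_equal(tf_opacity(tf2, 150), 0.15)
  expect_error(transfer_function(200, 100), "low_intensity")
})

test_that("shading follows the ambient + Lambertian model", {
  li <- light_set(directions = c(0, 0, 1), intensities = 1, ambient = 0.25)
  base <- c(0.8, 0.4, 0.2)
  # reflectivity 0: ambient * base only
  expect_equal(shade(c(0, 0, 1), 0, li, base), 0.25 * base)
  # white light along the normal, full reflectivity, no ambient: base colour
  li0 <- light_set(directions = c(0, 0, 1), intensities = 1, ambient = 0)
  expect_equal(shade(c(0, 0, 1), 1, li0, base), base)
  # light perpendicular to the normal: ambient only
  lip <- light_set(directions = c(1, 0, 0), intensities = 1, ambient = 0.25)
  expect_equal(shade(c(0, 0, 1), 1, lip, base), 0.25 * base)
  # coloured light multiplies channel-wise
  lc <- light_set(directions = c(0, 0, 1), intensities = 1,
                  colours = c(1, 0, 0), ambient = 0)
  expect_equal(shade(c(0, 0, 1), 1, lc, c(1, 1, 1)), c(1, 0, 0))
})

test_that("front-to-back compositing implements the over-operator", {
  # all transparent
  res <- composite_ray(matrix(1, 3, 3), c(0, 0, 0))
  expect_equal(res$colour, c(0, 0, 0))
  expect_equal(res$alpha, 0)
  # full occlusion by the first sample
  res <- composite_ray(rbind(c(1, 0, 0), c(0, 1, 0)), c(1, 0.8))
  expect_equal(res$colour, c(1, 0, 0))
  expect_equal(res$alpha, 1)
  # hand-computed two-sample over: C = 0.5 c1 + 0.25 c2, A = 0.75
  c1 <- c(1, 0, 0); c2 <- c(0, 0, 1)
  res <- composite_ray(rbind(c1, c2), c(0.5, 0.5))
  expect_equal(res$colour, 0.5 * c1 + 0.25 * c2)
  expect_equal(res$alpha, 0.75)
  # accumulated opacity is monotone and bounded
  set.seed(2)
  alphas <- runif(30)
  A <- 0
  for (al in alphas) {
    A2 <- A + (1 - A) * al
    expect_gte(A2, A)
    A <- A2
  }
  expect_lte(A, 1)
})

test_that("gradient direction at a shell surface is radial", {
  # anti-aliased rasterization: the surface gradient is the analytic normal
  # up to grid quantization (hard voxel classification gives staircase
  # gradients instead, which is why the renderer's visual checks use this mode)
  spec <- phantom_spec("solid_sphere", dims = c(32, 32, 32), radius = 10,
                       antialias = TRUE)
  ph <- phantom_generate(spec)
  v <- ph$volume
  # voxels just inside the surface, away from the axes
  set.seed(14)
  checked <- 0
  for (trial in 1:200) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    idx <- round((spec$center + spec$radius * u - v$origin) / v$spacing)
    g <- vol_gradient(v, idx)
    if (sqrt(sum(g^2)) < 1e-9) next
    radial <- (index_to_world(v, idx) - spec$center)
    cosang <- sum(-g * radial) / sqrt(sum(g^2)) / sqrt(sum(radial^2))
    ang <- acos(max(-1, min(1, cosang)))
    expect_lt(ang, 15 * pi / 180)
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("zero-opacity transfer functions render pure background", {
  ph <- two_shell_phantom(c(16, 16, 16))
  v <- ph$volume
  tf <- transfer_function(1e6, 2e6)
  li <- light_set(ambient = 1, background = c(0.2, 0.4, 0.6))
  img <- render_raycast(v, view_for_volume(v, image_px = 21), tf, li)
  for (ch in 1:3) {
    expect_true(all(abs(img$pixels[, , ch] - li$background[ch]) < 1e-12))
  }
})

test_that("an opaque uniform cube filling the view renders uniformly", {
  v <- new_volume(array(100, dim = c(16, 16, 16)))
  tf <- transfer_function(0, 1, max_opacity = 1)
  li <- light_set(directions = c(0, 0, -1), ambient = 0.3)
  view <- view_state(center = c(7.5, 7.5, 7.5), forward = c(0, 0, 1),
                     image_size = c(11, 11), pixel_pitch = 1)
  img <- render_raycast(v, view, tf, li)
  # interior pixels (rays that stay inside the cube) are identical
  inner <- img$pixels[3:9, 3:9, ]
  for (ch in 1:3) expect_equal(max(inner[, , ch]) - min(inner[, , ch]), 0)
  expect_gt(max(inner), 0)
})

test_that("sphere silhouette matches the analytic orthographic projection", {
  spec <- phantom_spec("solid_sphere", dims = c(32, 32, 32), radius = 10)
  ph <- phantom_generate(spec)
  v <- ph$volume
  tf <- transfer_function(50, 90)
  li <- light_set(directions = c(0, 0, -1), ambient = 0.2,
                  background = c(0, 0, 0))
  px <- 65
  view <- view_state(center = spec$center, forward = c(0, 0, 1),
                     image_size = c(px, px), pixel_pitch = 0.75)
  img <- render_raycast(v, view, tf, li)
  lum <- img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]
  fg <- lum > 1e-6
  # pixel-center distances from the view center, in world units
  offs <- ((0:(px - 1)) - (px - 1) / 2) * view$pixel_pitch
  dist <- sqrt(outer(offs^2, offs^2, "+"))
  band <- view$pixel_pitch  # one-pixel boundary band
  expect_true(all(fg[dist <= spec$radius - band]))
  expect_true(all(!fg[dist >= spec$radius + band]))
})

test_that("rendering is invariant to light permutation and zero lights", {
  ph <- two_shell_phantom(c(16, 16, 16))
  v <- ph$volume
  tf <- transfer_function(50, 90)
  view <- view_for_volume(v, image_px = 21)
  dirs <- rbind(c(0, 0, -1), c(1, 1, 0), c(0, -1, -1))
  cols <- rbind(c(1, 1, 1), c(1, 0.5, 0.2), c(0.3, 0.6, 1))
  ints <- c(0.8, 0.5, 0.4)
  li <- light_set(dirs, ints, cols, ambient = 0.1)
  perm <- c(3, 1, 2)
  li_perm <- light_set(dirs[perm, ], ints[perm], cols[perm, ], ambient = 0.1)
  li_zero <- light_set(rbind(dirs, c(0, 1, 0)), c(ints, 0),
                       rbind(cols, c(1, 1, 1)), ambient = 0.1)
  img <- render_raycast(v, view, tf, li)
  expect_equal(render_raycast(v, view, tf, li_perm)$pixels, img$pixels,
               tolerance = 1e-12)
  expect_equal(render_raycast(v, view, tf, li_zero)$pixels, img$pixels,
               tolerance = 1e-12)
})

test_that("90-degree view rotations of a symmetric phantom agree", {
  ph <- two_shell_phantom(c(32, 32, 32))
  v <- ph$volume
  tf <- transfer_function(50, 90)
  mkli <- function(fw) light_set(directions = -fw, ambient = 0.2)  # headlight
  views <- list(z = view_for_volume(v, forward = c(0, 0, 1), up = c(0, 1, 0)),
                x = view_for_volume(v, forward = c(1, 0, 0), up = c(0, 1, 0)),
                y = view_for_volume(v, forward = c(0, 1, 0), up = c(0, 0, 1)))
  imgs <- lapply(views, function(vw) render_raycast(v, vw, tf, mkli(vw$forward)))
  expect_lt(max_channel_diff(imgs$z, imgs$x), 5 / 255)
  expect_lt(max_channel_diff(imgs$z, imgs$y), 5 / 255)
  # in-plane 90-degree roll: image rotates with the up vector
  vz90 <- view_for_volume(v, forward = c(0, 0, 1), up = c(1, 0, 0))
  img90 <- render_raycast(v, vz90, tf, mkli(c(0, 0, 1)))
  rot <- img90$pixels
  for (ch in 1:3) rot[, , ch] <- t(img90$pixels[, , ch])[, dim(rot)[1]:1]
  expect_lt(max(abs(rot - imgs$z$pixels)), 5 / 255)
})

test_that("render presets load transfer function and lights from text", {
  f <- tempfile()
  writeLines(c("# surface preset", "low=50", "high=90", "max_opacity=0.8",
               "reflectivity_gain=1.5", "mode=surface", "ambient=0.15",
               "background=0.1,0.2,0.3", "light=0,0,-1,1,1,0.9,0.8",
               "light=1,0,0,0.5"), f)
  p <- read_render_preset(f)
  expect_equal(p$tf$low_intensity, 50)
  expect_equal(p$tf$max_opacity, 0.8)
  expect_equal(nrow(p$lights$directions), 2)
  expect_equal(p$lights$colours[1, ], c(1, 0.9, 0.8))
  expect_equal(p$lights$background, c(0.1, 0.2, 0.3))
})
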