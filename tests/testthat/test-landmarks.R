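write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("landmark lists load with running numbers and descriptions", {
  f <- write_lines_tmp("1 tip of coronoid process")
  defs <- load_landmark_list(f)
  expect_equal(nrow(defs), 1)
  expect_equal(defs$description, "tip of coronoid process")

  f12 <- write_lines_tmp(c("# cranial landmark set",
                           sprintf("%d type=%d landmark %d", 1:12,
                                   rep(1:3, each = 4), 1:12)))
  d12 <- load_landmark_list(f12)
  expect_equal(d12$number, 1:12)
  expect_equal(d12$lm_type, rep(1:3, each = 4))

  # gap in numbering errors with the offending line
  fgap <- write_lines_tmp(c("1 first", "3 third"))
  expect_error(load_landmark_list(fgap), "line 2")
  fdup <- write_lines_tmp(c("1 first", "1 again"))
  expect_error(load_landmark_list(fdup), "line 2")
  expect_error(load_landmark_list(write_lines_tmp("# only a comment")), "empty")
  expect_error(load_landmark_list(tempfile()), "not found")
})

test_that("symmetry maps validate midline/pair structure", {
  defs <- landmark_defs(1:4, paste("lm", 1:4))
  m <- symmetry_map(c(1, 2), rbind(c(3, 4)), defs)
  expect_equal(m$midline, c(1L, 2L))
  expect_equal(nrow(m$pairs), 1)
  expect_error(symmetry_map(integer(0), rbind(c(3, 3)), defs), "itself")
  expect_error(symmetry_map(integer(0), rbind(c(3, 99)), defs), "unknown")
  expect_error(symmetry_map(c(3), rbind(c(3, 4)), defs), "both midline and paired")
  expect_error(symmetry_map(integer(0), rbind(c(1, 2), c(2, 3)), defs),
               "more than one pair")

  f <- write_lines_tmp(c("# symmetry", "midline 1 2", "pair 3 4"))
  m2 <- load_symmetry_map(f, defs)
  expect_equal(m2$pairs[1, ], c(left = 3L, right = 4L))
  # linking line endpoints come from the marked coordinates
  set <- new_landmark_set(defs)
  set <- mark_point(set, 3, c(1, 2, 3))
  set <- mark_point(set, 4, c(4, 5, 6))
  ll <- linking_lines(set, m2)
  expect_equal(unlist(ll[1, c("lx", "ly", "lz", "rx", "ry", "rz")],
                      use.names = FALSE),
               c(1, 2, 3, 4, 5, 6))
})

test_that("marking stores, overwrites with notice, and jump returns exactly", {
  defs <- landmark_defs(1, "only point")
  set <- new_landmark_set(defs)
  set <- mark_point(set, 1, c(10, 12, 8))
  expect_equal(unname(set$coords[1, ]), c(10, 12, 8))
  expect_message(set <- mark_point(set, 1, c(11, 12, 8)), "re-marking")
  expect_equal(unname(set$coords[1, ]), c(11, 12, 8))
  expect_error(mark_point(set, 5, c(0, 0, 0)), "unknown landmark number 5")
  expect_identical(jump_stored(set, 1), c(11, 12, 8))
  expect_error(jump_stored(new_landmark_set(defs), 1), "not been marked")
})

test_that("TPS files serialize and round-trip exactly at written precision", {
  defs <- landmark_defs(1, "tip")
  set <- new_landmark_set(defs, specimen_id = "spec A1")
  set <- mark_point(set, 1, c(10, 12, 8))
  f <- tempfile(fileext = ".tps")
  export_tps(set, f)
  expect_identical(readLines(f),
                   c("LM3=1", "10.000000 12.000000 8.000000", "ID=spec A1"))
  # 12 random landmarks round-trip
  d12 <- landmark_defs(1:12, paste("lm", 1:12))
  s12 <- new_landmark_set(d12, "s12")
  set.seed(9)
  coords <- matrix(round(runif(36, 0, 100), 6), 12, 3)
  for (i in 1:12) s12 <- mark_point(s12, i, coords[i, ])
  f12 <- tempfile()
  export_tps(s12, f12)
  back <- read_tps(f12)
  expect_equal(unname(back$coords), unname(coords))
  expect_equal(back$specimen_id, "s12")
  # strict export with an unmarked landmark names it
  s11 <- new_landmark_set(d12)
  for (i in setdiff(1:12, 7)) s11 <- mark_point(s11, i, coords[i, ])
  expect_error(export_tps(s11, tempfile()), "7")
  expect_silent(export_tps(s11, tempfile(), strict = FALSE))
  # voxel units divide by spacing
  fv <- tempfile()
  export_tps(set, fv, units = "voxel", spacing = c(0.5, 2, 4))
  expect_equal(unname(read_tps(fv)$coords[1, ]), c(20, 6, 2))
})

test_that("NTSYS matrices carry the documented header and round-trip", {
  d1 <- landmark_defs(1, "pt")
  s1 <- mark_point(new_landmark_set(d1, "sp1"), 1, c(1, 2, 3))
  f <- tempfile()
  export_ntsys(list(s1), f)
  expect_identical(readLines(f)[1], "1 1 3 0")

  d12 <- landmark_defs(1:12, paste("lm", 1:12))
  set.seed(10)
  mk <- function(id) {
    s <- new_landmark_set(d12, id)
    for (i in 1:12) s <- mark_point(s, i, round(runif(3, 0, 50), 6))
    s
  }
  sa <- mk("a"); sb <- mk("b")
  f2 <- tempfile()
  export_ntsys(list(sa, sb), f2)
  expect_identical(readLines(f2)[1], "1 2 36 0")
  back <- read_ntsys(f2)
  expect_equal(unname(back$coords[[1]]), unname(sa$coords))
  expect_equal(unname(back$coords[[2]]), unname(sb$coords))
  expect_equal(back$specimen_ids, c("a", "b"))
  # mismatched defs across specimens
  s1b <- mark_point(new_landmark_set(d1, "x"), 1, c(0, 0, 0))
  expect_error(export_ntsys(list(sa, s1b), tempfile()), "same landmark")
})

test_that("TPS and NTSYS exports of the same data decode identically", {
  d <- landmark_defs(1:5, paste("lm", 1:5))
  s <- new_landmark_set(d, "sp")
  set.seed(12)
  for (i in 1:5) s <- mark_point(s, i, round(runif(3, 0, 30), 6))
  ft <- tempfile(); fn <- tempfile()
  export_tps(s, ft)
  export_ntsys(list(s), fn)
  expect_equal(read_tps(ft)$coords, read_ntsys(fn)$coords[[1]])
})

test_that("precision statistic reproduces the hand-computed median example", {
  defs <- landmark_defs(1, "pt", lm_type = 3)
  reps <- lapply(c(0, 0, 3), function(x) {
    mark_point(new_landmark_set(defs), 1, c(x, 5, 5))
  })
  st <- precision_stats(reps, defs, spacing = c(1, 1, 1))
  expect_equal(sort(st$distances$distance), c(0, 0, 3))
  # identical repeats give all-zero distances
  reps0 <- lapply(1:3, function(i) mark_point(new_landmark_set(defs), 1, c(1, 2, 3)))
  expect_true(all(precision_stats(reps0, defs)$distances$distance == 0))
})

test_that("precision statistic is invariant to repeat order and translation", {
  defs <- landmark_defs(1:4, paste("lm", 1:4), lm_type = c(1, 1, 2, 3))
  set.seed(20)
  reps <- lapply(1:6, function(r) {
    s <- new_landmark_set(defs)
    for (i in 1:4) s <- mark_point(s, i, c(10 * i, 5, 5) + rnorm(3))
    s
  })
  st <- precision_stats(reps, defs, spacing = c(0.5, 0.5, 1))
  st_shuffled <- precision_stats(reps[c(4, 2, 6, 1, 5, 3)], defs,
                                 spacing = c(0.5, 0.5, 1))
  expect_equal(sort(st$distances$distance), sort(st_shuffled$distances$distance))
  shift <- c(100, -50, 7)
  reps_t <- lapply(reps, function(s) { s$coords <- sweep(s$coords, 2, shift, "+"); s })
  st_t <- precision_stats(reps_t, defs, spacing = c(0.5, 0.5, 1))
  expect_equal(st_t$distances$distance, st$distances$distance, tolerance = 1e-9)
})

test_that("per-type jitter recovers ordered, calibrated median distances", {
  # 10 repeats x 12 landmarks, per-type isotropic Gaussian jitter sigma =
  # 0.5 / 1 / 2 voxels; the radial distance of a 3D Gaussian has median
  # sigma * sqrt(qchisq(0.5, 3))
  defs <- landmark_defs(1:12, paste("lm", 1:12), lm_type = rep(1:3, each = 4))
  sig <- c(0.5, 1, 2)[defs$lm_type]
  true_pos <- matrix(runif(36, 20, 80), 12, 3)
  set.seed(123)
  reps <- lapply(1:10, function(r) {
    s <- new_landmark_set(defs)
    for (i in 1:12) s <- mark_point(s, i, true_pos[i, ] + rnorm(3, 0, sig[i]))
    s
  })
  st <- precision_stats(reps, defs, spacing = c(1, 1, 1))
  med <- st$summary$median
  expect_true(all(diff(med) > 0))  # type1 < type2 < type3
  theo <- c(0.5, 1, 2) * sqrt(qchisq(0.5, 3))
  expect_true(all(abs(med - theo) / theo < 0.25))
})

test_that("mirror-symmetric landmark sets pass the reflection pairing check", {
  spec <- phantom_spec("mirror_blobs", dims = c(48, 32, 32), radius = 7,
                       blob_offset = 12)
  ph <- phantom_generate(spec)
  n <- nrow(ph$landmarks)
  defs <- landmark_defs(1:n, rownames(ph$landmarks))
  set <- new_landmark_set(defs, "mirror")
  for (i in 1:n) set <- mark_point(set, i, ph$landmarks[i, ])
  pl <- plane_from_points(ph$plane_points[1, ], ph$plane_points[2, ],
                          ph$plane_points[3, ])
  pairs <- cbind(match(ph$pairs$left, rownames(ph$landmarks)),
                 match(ph$pairs$right, rownames(ph$landmarks)))
  map <- symmetry_map(integer(0), pairs, defs)
  for (r in seq_len(nrow(map$pairs))) {
    left <- set$coords[map$pairs[r, 1], ]
    right <- set$coords[map$pairs[r, 2], ]
    expect_lt(sqrt(sum((reflect_point(pl, left) - right)^2)), 1)
  }
})

test_that("the bundled example landmark and symmetry files load", {
  lmf <- system.file("extdata", "example_landmarks.txt", package = "voxmark")
  smf <- system.file("extdata", "example_symmetry.txt", package = "voxmark")
  defs <- load_landmark_list(lmf)
  expect_equal(nrow(defs), 9)
  expect_equal(defs$lm_type[c(1, 4, 8)], c(1L, 3L, 2L))
  map <- load_symmetry_map(smf, defs)
  expect_equal(map$midline, 1:5)
  expect_equal(nrow(map$pairs), 2)
  pf <- system.file("extdata", "phantom_surface_preset.txt", package = "voxmark")
  p <- read_render_preset(pf)
  expect_equal(p$tf$low_intensity, 50)
  expect_equal(nrow(p$lights$directions), 2)
})
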