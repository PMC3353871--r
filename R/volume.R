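#' Voxel volume container
#'
#' A `volume` wraps a 3D scalar intensity grid together with its physical
#' geometry. Intensities are stored as doubles (monotone in physical
#' density). The grid is indexed `data[i+1, j+1, k+1]` for the 0-based voxel
#' index `(i, j, k)` with `i` along x (column), `j` along y (row) and `k`
#' along z (slice). A voxel index refers to the voxel *center*:
#' `world(i,j,k) = origin + (i*sx, j*sy, k*sz)`.
#'
#' @param data 3D numeric array of intensities, dim `(nx, ny, nz)`.
#' @param spacing physical units per voxel on each axis, strictly positive.
#' @param origin world position of voxel index `(0,0,0)`.
#' @param downsample_factors integer factors `(fx, fy, fz)` of averaging
#'   already applied to this grid (provenance; `c(1,1,1)` for raw data).
#' @return An object of class `volume` with fields `data`, `dims`,
#'   `spacing`, `origin`, `downsample_factors`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       downsample_factors = c(1L, 1L, 1L)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive numbers", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be 3 finite numbers", call. = FALSE)
  }
  f <- as.integer(downsample_factors)
  if (length(f) != 3L || any(is.na(f)) || any(f < 1L)) {
    stop("downsample_factors must be 3 integers >= 1", call. = FALSE)
  }
  storage.mode(data) <- "double"
  structure(
    list(data = data, dims = dim(data), spacing = spacing, origin = origin,
         downsample_factors = f),
    class = "volume"
  )
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %d x %d x %d voxels, spacing (%g, %g, %g), origin (%g, %g, %g)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range [%g, %g], downsample factors (%d, %d, %d)\n",
              min(x$data), max(x$data),
              x$downsample_factors[1], x$downsample_factors[2],
              x$downsample_factors[3]))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

#' World-coordinate bounds of the voxel-center grid
#'
#' @param v a volume.
#' @return 2x3 matrix: row 1 the world position of voxel (0,0,0), row 2 of
#'   voxel (nx-1, ny-1, nz-1).
#' @export
vol_bounds <- function(v) {
  rbind(lo = v$origin, hi = v$origin + (v$dims - 1) * v$spacing)
}

#' Convert 0-based voxel indices to world coordinates (voxel centers)
#'
#' @param v a volume.
#' @param idx numeric vector of length 3 or an n x 3 matrix of (possibly
#'   fractional) 0-based voxel indices.
#' @return world coordinates, same shape as `idx`.
#' @export
index_to_world <- function(v, idx) {
  if (is.matrix(idx)) {
    sweep(sweep(idx, 2, v$spacing, "*"), 2, v$origin, "+")
  } else {
    v$origin + idx * v$spacing
  }
}

#' Convert world coordinates to continuous 0-based voxel indices
#'
#' @param v a volume.
#' @param p world point (length 3) or n x 3 matrix.
#' @return continuous voxel indices, same shape as `p`.
#' @export
world_to_index <- function(v, p) {
  if (is.matrix(p)) {
    sweep(sweep(p, 2, v$origin, "-"), 2, v$spacing, "/")
  } else {
    (p - v$origin) / v$spacing
  }
}

#' Trilinear intensity interpolation at world points
#'
#' Points are clamped to the voxel-center bounding box before sampling, so
#' values at or beyond the border equal the border voxel values.
#'
#' @param v a volume.
#' @param pts n x 3 matrix of world coordinates (or length-3 vector).
#' @return numeric vector of n interpolated intensities.
#' @export
vol_interp <- function(v, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  u <- world_to_index(v, pts)
  d <- v$dims
  for (a in 1:3) u[, a] <- clamp(u[, a], 0, d[a] - 1)
  i0 <- floor(u)
  for (a in 1:3) i0[, a] <- pmin(i0[, a], max(d[a] - 2, 0))
  i1 <- sweep(i0 + 1, 2, d - 1, pmin)
  f <- u - i0
  a <- v$data
  g <- function(ix, iy, iz) a[cbind(ix + 1, iy + 1, iz + 1)]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- g(i0[, 1], i0[, 2], i0[, 3]) * (1 - fx) + g(i1[, 1], i0[, 2], i0[, 3]) * fx
  c10 <- g(i0[, 1], i1[, 2], i0[, 3]) * (1 - fx) + g(i1[, 1], i1[, 2], i0[, 3]) * fx
  c01 <- g(i0[, 1], i0[, 2], i1[, 3]) * (1 - fx) + g(i1[, 1], i0[, 2], i1[, 3]) * fx
  c11 <- g(i0[, 1], i1[, 2], i1[, 3]) * (1 - fx) + g(i1[, 1], i1[, 2], i1[, 3]) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Output dimensions of block-average down-sampling
#'
#' Trailing voxels that do not fill a complete block are dropped, so each
#' output voxel is an equal-weight mean of a full `fx x fy x fz` block.
#'
#' @param dims input grid dims (3 positive integers).
#' @param factors averaging factors (3 integers >= 1).
#' @return integer vector `floor(dims / factors)`.
#' @export
downsampled_dims <- function(dims, factors) {
  dims <- as.integer(dims); factors <- as.integer(factors)
  if (any(factors < 1L)) stop("factors must be >= 1", call. = FALSE)
  if (any(factors > dims)) {
    stop("down-sampling factor exceeds grid dimension", call. = FALSE)
  }
  dims %/% factors
}

#' Down-sample a volume by block averaging
#'
#' Each output voxel is the arithmetic mean of its `fx x fy x fz` input
#' block; spacing is multiplied by the factors, and the origin moves to the
#' center of the first block (voxel-center convention). Trailing partial
#' blocks are dropped.
#'
#' @param v a volume.
#' @param factors `(fx, fy, fz)` integers >= 1.
#' @return the down-sampled volume; `downsample_factors` accumulates.
#' @export
downsample <- function(v, factors) {
  stopifnot(is_volume(v))
  f <- as.integer(factors)
  nd <- downsampled_dims(v$dims, f)
  if (all(f == 1L)) return(v)
  a <- v$data[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]), seq_len(nd[3] * f[3]),
              drop = FALSE]
  # reshape to (fx, nx', fy, ny', fz, nz'), bring the block axes first and
  # reduce them with one sequential mean per block (x fastest, then y, z)
  dim(a) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(prod(f), prod(nd))
  m <- colSums(a) / prod(f)
  dim(m) <- nd
  new_volume(m,
             spacing = v$spacing * f,
             origin = v$origin + (f - 1) / 2 * v$spacing,
             downsample_factors = v$downsample_factors * f)
}

#' Intensity gradient at a voxel, in world units
#'
#' Central differences scaled by 1/spacing per axis; one-sided differences
#' at the grid border. The gradient's norm drives surface reflectivity in
#' rendering; its direction approximates the (inward) surface normal of
#' bright structures.
#'
#' @param v a volume.
#' @param index 0-based voxel index `(i, j, k)`.
#' @return world-space gradient vector (length 3).
#' @export
vol_gradient <- function(v, index) {
  idx <- as.integer(round(index))
  d <- v$dims
  if (any(idx < 0L) || any(idx >= d)) stop("voxel index out of bounds", call. = FALSE)
  g <- numeric(3)
  for (a in 1:3) {
    ip <- idx; im <- idx
    ip[a] <- min(idx[a] + 1L, d[a] - 1L)
    im[a] <- max(idx[a] - 1L, 0L)
    span <- (ip[a] - im[a]) * v$spacing[a]
    if (span == 0) next  # degenerate single-voxel axis
    g[a] <- (v$data[ip[1] + 1, ip[2] + 1, ip[3] + 1] -
               v$data[im[1] + 1, im[2] + 1, im[3] + 1]) / span
  }
  g
}

# precompute the three central-difference gradient component grids
# (world units); used by the renderer to sample gradients trilinearly
vol_gradient_grids <- function(v) {
  d <- v$dims
  out <- vector("list", 3)
  for (a in 1:3) {
    n <- d[a]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * v$spacing[a]
    denom[denom == 0] <- 1
    hi <- switch(a, v$data[ip, , , drop = FALSE], v$data[, ip, , drop = FALSE],
                 v$data[, , ip, drop = FALSE])
    lo <- switch(a, v$data[im, , , drop = FALSE], v$data[, im, , drop = FALSE],
                 v$data[, , im, drop = FALSE])
    out[[a]] <- sweep(hi - lo, a, denom, "/")
  }
  names(out) <- c("gx", "gy", "gz")
  out
}

# --- portable binary fixture container -------------------------------------

VOL_MAGIC <- charToRaw("VOXVOL01")

#' Write a volume to a portable binary fixture file
#'
#' Little-endian container with an explicit header (magic, dims, spacing,
#' origin, down-sample factors) followed by the raw double grid. Lossless;
#' intended for test fixtures and session scripts, not clinical use.
#'
#' @param v a volume.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(VOL_MAGIC, con)
  writeBin(as.integer(v$dims), con, size = 4, endian = "little")
  writeBin(as.double(v$spacing), con, size = 8, endian = "little")
  writeBin(as.double(v$origin), con, size = 8, endian = "little")
  writeBin(as.integer(v$downsample_factors), con, size = 4, endian = "little")
  writeBin(as.double(v$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a volume fixture written by [write_volume()]
#'
#' @param path file path.
#' @return a volume, bit-identical to the one written.
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(VOL_MAGIC))
  if (length(magic) < length(VOL_MAGIC) || !identical(magic, VOL_MAGIC)) {
    stop("not a volume fixture file (bad magic): ", path, call. = FALSE)
  }
  dims <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  spacing <- readBin(con, "double", n = 3, size = 8, endian = "little")
  origin <- readBin(con, "double", n = 3, size = 8, endian = "little")
  f <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  if (length(dims) < 3 || length(spacing) < 3 || length(origin) < 3 ||
      length(f) < 3 || any(dims <= 0)) {
    stop("truncated or corrupt volume fixture: ", path, call. = FALSE)
  }
  n <- prod(dims)
  data <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(data) != n) {
    stop("truncated volume fixture (expected ", n, " voxels, got ",
         length(data), "): ", path, call. = FALSE)
  }
  dim(data) <- dims
  new_volume(data, spacing = spacing, origin = origin, downsample_factors = f)
}
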