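# Independent brute-force oracles used across test files. These stay
# deliberately naive (explicit loops, fine stepping) so they share no code
# path with the implementation they check.

# block-mean down-sampling by explicit loops: sum/size per full block
oracle_downsample <- function(a, f) {
  d <- dim(a)
  nd <- d %/% f
  out <- array(NA_real_, nd)
  for (k in seq_len(nd[3])) for (j in seq_len(nd[2])) for (i in seq_len(nd[1])) {
    block <- a[((i - 1) * f[1] + 1):(i * f[1]),
               ((j - 1) * f[2] + 1):(j * f[2]),
               ((k - 1) * f[3] + 1):(k * f[3])]
    out[i, j, k] <- sum(block) / length(block)
  }
  out
}

# fine-step ray traversal: march at 0.05 * min(spacing) over the ray's
# intersection with the voxel-center box, find the first supra-threshold
# sample and refine the crossing by linear interpolation between the
# bracketing fine samples (different traversal and refinement than the
# implementation's coarse march + bisection)
oracle_first_hit <- function(v, base, dir, threshold) {
  dir <- dir / sqrt(sum(dir^2))
  b <- vol_bounds(v)
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(dir[a]) < 1e-14) {
      if (base[a] < b[1, a] || base[a] > b[2, a]) return(NULL)
    } else {
      ta <- (b[1, a] - base[a]) / dir[a]; tb <- (b[2, a] - base[a]) / dir[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (!(t0 <= t1)) return(NULL)
  step <- 0.05 * min(v$spacing)
  ts <- seq(t0, t1, by = step)
  prev_t <- NULL; prev_val <- NULL
  for (t in ts) {
    val <- vol_interp(v, base + t * dir)
    if (val > threshold) {
      if (is.null(prev_t)) return(base + t * dir)
      # linear interpolation of the crossing within the bracketing pair
      frac <- (threshold - prev_val) / (val - prev_val)
      tc <- prev_t + frac * (t - prev_t)
      return(base + tc * dir)
    }
    prev_t <- t; prev_val <- val
  }
  NULL
}

# random rays guaranteed to pass near a phantom's center
random_center_rays <- function(center, n, jitter = 3) {
  dirs <- matrix(stats::rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  targets <- matrix(center, n, 3, byrow = TRUE) +
    matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
  bases <- targets - 100 * dirs
  list(bases = bases, dirs = dirs)
}

# standard two-shell phantom used by the picking / rendering batteries;
# geometry scales with the grid so small volumes stay valid
two_shell_phantom <- function(dims = c(32, 32, 32)) {
  ext <- min((dims - 1) / 2)
  r <- 0.75 * ext
  phantom_generate(phantom_spec("two_shell", dims = dims, radius = r,
                                shell_thickness = max(2, r / 5),
                                inner_radius = r / 2))
}

max_channel_diff <- function(img_a, img_b) {
  max(abs(img_a$pixels - img_b$pixels))
}

# orthonormality + right-handedness residual of a view frame
frame_error <- function(view) {
  M <- rbind(view$right, view$up, view$forward)
  cr <- c(view$right[2] * view$up[3] - view$right[3] * view$up[2],
          view$right[3] * view$up[1] - view$right[1] * view$up[3],
          view$right[1] * view$up[2] - view$right[2] * view$up[1])
  max(abs(M %*% t(M) - diag(3)), abs(cr - view$forward))
}
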