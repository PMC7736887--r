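# Internal array and RNG utilities.

# Evaluate expr with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_congruent <- function(a, b, what = "objects") {
  if (!identical(dim(voxelData(a)), dim(voxelData(b))) ||
      max(abs(voxelSpacing(a) - voxelSpacing(b))) > 1e-9)
    stop(what, " must share grid shape and spacing", call. = FALSE)
  invisible(TRUE)
}

# Truncated, renormalized 1D Gaussian kernel; sigma in voxel units.
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  if (sigma <= 0) return(1)
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 3D array; fwhm in mm, spacing mm/axis.
gaussian_blur3d <- function(arr, fwhm, spacing) {
  if (fwhm <= 0) return(arr)
  sig_vox <- (fwhm / 2.3548200450309493) / spacing
  d <- dim(arr)
  for (ax in 1:3) {
    if (sig_vox[ax] <= 0) next
    k <- gaussian_kernel(sig_vox[ax])
    arr <- conv3d_axis(arr, d, k, ax)
  }
  arr
}

# Block-average a 3D array by integer factors (preserves the mean, hence
# total activity x volume).
block_average <- function(arr, factors) {
  d <- dim(arr)
  f <- as.integer(factors)
  if (any(d %% f != 0))
    stop("grid dimensions must be divisible by the downsampling factors",
         call. = FALSE)
  nd <- d %/% f
  a <- colMeans(matrix(arr, nrow = f[1]))
  dim(a) <- c(nd[1], d[2], d[3])
  a <- aperm(a, c(2, 1, 3))
  a <- colMeans(matrix(a, nrow = f[2]))
  dim(a) <- c(nd[2], nd[1], d[3])
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  a <- colMeans(matrix(a, nrow = f[3]))
  dim(a) <- c(nd[3], nd[1], nd[2])
  aperm(a, c(2, 3, 1))
}

# Offsets (voxel index deltas) whose centers lie within `radius_mm` of the
# origin, for the given spacing. Returns an integer matrix n x 3.
sphere_offsets <- function(radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  g <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2
  m <- g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# Cylinder offsets: in-plane (axes 1,2) radius and half-height along axis 3.
cylinder_offsets <- function(radius_mm, half_height_mm, spacing) {
  r <- floor(c(radius_mm / spacing[1:2], half_height_mm / spacing[3]))
  g <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2
  keep <- d2 <= radius_mm^2 + 1e-9 &
    abs(g[, 3] * spacing[3]) <= half_height_mm + 1e-9
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

# 26-connected component of `supra` (logical array) containing seed index
# (length-3 integer). Returns a logical array.
connected_component26 <- function(supra, seed_idx) {
  d <- dim(supra)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  comp <- array(FALSE, d)
  lin <- function(ijk) ijk[, 1] + d[1] * (ijk[, 2] - 1L) +
    d[1] * d[2] * (ijk[, 3] - 1L)
  frontier <- matrix(as.integer(seed_idx), ncol = 3)
  comp[lin(frontier)] <- TRUE
  while (nrow(frontier)) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                     drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
      cand[, 2] >= 1L & cand[, 2] <= d[2] &
      cand[, 3] >= 1L & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    li <- lin(cand)
    keep <- supra[li] & !comp[li]
    li <- unique(li[keep])
    if (!length(li)) break
    comp[li] <- TRUE
    frontier <- arrayInd(li, d)
  }
  comp
}

# Trilinear interpolation of arr (spacing/origin in mm) at points (n x 3, mm).
# Points outside the grid are clamped to the boundary.
trilinear_interp <- function(arr, spacing, origin, pts) {
  d <- dim(arr)
  fx <- pmin(pmax((pts[, 1] - origin[1]) / spacing[1], 0), d[1] - 1)
  fy <- pmin(pmax((pts[, 2] - origin[2]) / spacing[2], 0), d[2] - 1)
  fz <- pmin(pmax((pts[, 3] - origin[3]) / spacing[3], 0), d[3] - 1)
  i0 <- pmin(floor(fx), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(fz), d[3] - 2); k0 <- pmax(k0, 0)
  if (d[1] == 1) i0 <- rep(0, length(fx))
  if (d[2] == 1) j0 <- rep(0, length(fy))
  if (d[3] == 1) k0 <- rep(0, length(fz))
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  at <- function(di, dj, dk) {
    ii <- pmin(i0 + di, d[1] - 1); jj <- pmin(j0 + dj, d[2] - 1)
    kk <- pmin(k0 + dk, d[3] - 1)
    arr[1 + ii + d[1] * jj + d[1] * d[2] * kk]
  }
  at(0, 0, 0) * (1 - tx) * (1 - ty) * (1 - tz) +
    at(1, 0, 0) * tx * (1 - ty) * (1 - tz) +
    at(0, 1, 0) * (1 - tx) * ty * (1 - tz) +
    at(1, 1, 0) * tx * ty * (1 - tz) +
    at(0, 0, 1) * (1 - tx) * (1 - ty) * tz +
    at(1, 0, 1) * tx * (1 - ty) * tz +
    at(0, 1, 1) * (1 - tx) * ty * tz +
    at(1, 1, 1) * tx * ty * tz
}

# Bounding box (list lo, hi index vectors) of a logical array, with an
# optional margin in voxels, clipped to the grid.
mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask)
  if (!length(idx)) stop("empty mask", call. = FALSE)
  ijk <- arrayInd(idx, dim(mask))
  lo <- pmax(apply(ijk, 2, min) - margin, 1L)
  hi <- pmin(apply(ijk, 2, max) + margin, dim(mask))
  list(lo = as.integer(lo), hi = as.integer(hi))
}
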