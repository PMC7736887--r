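# First-order, GLCM and NGTDM features, computed from first principles.

# 13 unique 3D directions at Chebyshev distance 1 (one per +/- pair)
glcm_directions <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

# levels array shifted by `off`; NA-filled at the border
shift_levels <- function(lev, off) {
  d <- dim(lev)
  out <- array(NA_integer_, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (off[a] >= 0) {
      dst[[a]] <- seq_len(d[a] - off[a])
      src[[a]] <- seq_len(d[a] - off[a]) + off[a]
    } else {
      dst[[a]] <- seq_len(d[a] + off[a]) - off[a]
      src[[a]] <- seq_len(d[a] + off[a])
    }
    if (length(src[[a]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- lev[src[[1]], src[[2]], src[[3]]]
  out
}

#' Intensity (first-order) features
#'
#' Entropy and uniformity are computed on the fixed-bin-width
#' discretized histogram; skewness, kurtosis (Pearson, un-excess) and
#' standard deviation on the raw in-mask values with population
#' (uncorrected) central moments.
#'
#' @param image \linkS4class{UptakeVolume}.
#' @param mask \linkS4class{VoiMask} with >= 2 voxels.
#' @param disc \linkS4class{DiscretizedVolume} for the same mask.
#' @return List: entropy (bits), uniformity, skewness, kurtosis,
#'   standard_deviation, degenerate (TRUE when the ROI has zero
#'   variance, in which case skewness and kurtosis are 0).
#' @export
intensityFeatures <- function(image, mask, disc) {
  stopifnot(is(image, "UptakeVolume"), is(mask, "VoiMask"),
            is(disc, "DiscretizedVolume"))
  vals <- image@data[mask@data]
  if (length(vals) < 2) stop("need >= 2 in-mask voxels", call. = FALSE)
  lv <- disc@levels[mask@data]
  q <- tabulate(lv, nbins = disc@nLevels)
  q <- q[q > 0] / length(lv)
  m <- mean(vals)
  m2 <- mean((vals - m)^2)
  degenerate <- m2 == 0
  list(
    entropy = -sum(q * log2(q)),
    uniformity = sum(q^2),
    skewness = if (degenerate) 0 else mean((vals - m)^3) / m2^1.5,
    kurtosis = if (degenerate) 0 else mean((vals - m)^4) / m2^2,
    standard_deviation = sqrt(m2),
    degenerate = degenerate)
}

# averaged symmetric co-occurrence matrix over the 13 directions
glcm_matrix <- function(disc) {
  lev <- disc@levels
  ng <- disc@nLevels
  dirs <- glcm_directions()
  acc <- matrix(0, ng, ng)
  ndir <- 0L
  for (r in seq_len(nrow(dirs))) {
    sh <- shift_levels(lev, dirs[r, ])
    ok <- !is.na(lev) & !is.na(sh)
    if (!any(ok)) next
    i <- lev[ok]; j <- sh[ok]
    cnt <- matrix(tabulate(i + ng * (j - 1L), nbins = ng * ng), ng, ng)
    cnt <- cnt + t(cnt)                      # symmetric pairs
    acc <- acc + cnt / sum(cnt)              # normalize per direction
    ndir <- ndir + 1L
  }
  if (ndir == 0L)
    stop("no in-mask voxel pairs in any direction", call. = FALSE)
  acc / ndir
}

#' GLCM texture features
#'
#' The gray-level co-occurrence matrix is built per direction (13 unique
#' 3D directions at nearest-neighbor distance 1) over in-mask voxel
#' pairs, symmetrized, normalized to sum 1, and the normalized matrices
#' are averaged uniformly over directions having at least one pair.
#' Features are computed from the averaged matrix; logs are base 2.
#'
#' @param disc \linkS4class{DiscretizedVolume}.
#' @return List: contrast, correlation, inverse_difference,
#'   normalized_inverse_difference, joint_energy, joint_entropy,
#'   degenerate (TRUE for a constant ROI, where correlation is defined
#'   as 1).
#' @export
glcmFeatures <- function(disc) {
  p <- glcm_matrix(disc)
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_ <- rowSums(p)
  mu <- sum(seq_len(ng) * pi_)
  s2 <- sum((seq_len(ng) - mu)^2 * pi_)
  degenerate <- s2 == 0
  pp <- p[p > 0]
  list(
    contrast = sum((i - j)^2 * p),
    correlation = if (degenerate) 1 else
      sum((i - mu) * (j - mu) * p) / s2,
    inverse_difference = sum(p / (1 + abs(i - j))),
    normalized_inverse_difference = sum(p / (1 + abs(i - j) / ng)),
    joint_energy = sum(p^2),
    joint_entropy = -sum(pp * log2(pp)),
    degenerate = degenerate)
}

#' NGTDM texture features
#'
#' The neighborhood gray-tone difference matrix uses 26-neighborhoods
#' restricted to in-mask voxels: for each level i, n_i counts its
#' voxels, p_i = n_i / N, and s_i sums |i - mean level of the in-mask
#' neighbors| over those voxels. Voxels without any in-mask neighbor
#' are excluded from N. Coarseness is capped at 1e6 for flat regions;
#' strength and contrast are 0 when their denominators vanish.
#'
#' @param disc \linkS4class{DiscretizedVolume}.
#' @return List: busyness, coarseness, complexity, contrast, strength.
#' @export
ngtdmFeatures <- function(disc) {
  lev <- disc@levels
  ng <- disc@nLevels
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  nb_sum <- array(0, dim(lev))
  nb_cnt <- array(0L, dim(lev))
  for (r in seq_len(nrow(off))) {
    sh <- shift_levels(lev, off[r, ])
    ok <- !is.na(sh)
    nb_sum[ok] <- nb_sum[ok] + sh[ok]
    nb_cnt <- nb_cnt + ok
  }
  valid <- !is.na(lev) & nb_cnt > 0L
  if (!any(valid))
    stop("no in-mask voxel has an in-mask neighbor", call. = FALSE)
  li <- lev[valid]
  dev <- abs(li - nb_sum[valid] / nb_cnt[valid])
  N <- length(li)
  n_i <- tabulate(li, nbins = ng)
  s_i <- vapply(seq_len(ng), function(k) sum(dev[li == k]), numeric(1))
  p_i <- n_i / N
  pres <- which(p_i > 0)
  ngp <- length(pres)
  lv <- pres
  pv <- p_i[pres]
  sv <- s_i[pres]
  ps <- sum(pv * sv)
  coarseness <- if (ps == 0) 1e6 else min(1 / ps, 1e6)
  ij_d2 <- outer(lv, lv, "-")^2
  contrast <- if (ngp <= 1) 0 else
    (sum(outer(pv, pv) * ij_d2) / (ngp * (ngp - 1))) * (sum(sv) / N)
  ipd <- outer(lv * pv, lv * pv, "-")
  den_b <- sum(abs(ipd[row(ipd) != col(ipd)]))
  busyness <- if (den_b == 0) 0 else ps / den_b
  psm <- outer(pv * sv, pv * sv, "+")
  pvs <- outer(pv, pv, "+")
  offdiag <- row(psm) != col(psm)
  complexity <- sum((abs(outer(lv, lv, "-")) * psm / pvs)[offdiag]) / N
  strength <- if (sum(sv) == 0) 0 else
    sum((pvs * ij_d2)[offdiag]) / sum(sv)
  list(busyness = busyness, coarseness = coarseness,
       complexity = complexity, contrast = contrast, strength = strength)
}
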