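# Independent brute-force reference implementations, used by the test
# suite and the acceptance script to cross-check the vectorized feature
# code. Deliberately naive: explicit loops, no shared code with R/.

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# blurred value at the center of a uniform sphere (radius R, amplitude A)
# convolved with an isotropic Gaussian of sd sigma (closed form)
oracle_sphere_center <- function(R, sigma, A = 1) {
  A * (erf(R / (sqrt(2) * sigma)) -
         sqrt(2 / pi) * (R / sigma) * exp(-R^2 / (2 * sigma^2)))
}

oracle_glcm_matrix <- function(lev) {
  ng <- max(lev, na.rm = TRUE)
  d <- dim(lev)
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  dirs <- dirs[dirs[, 3] > 0 | (dirs[, 3] == 0 & dirs[, 2] > 0) |
                 (dirs[, 3] == 0 & dirs[, 2] == 0 & dirs[, 1] > 0), ,
               drop = FALSE]
  acc <- matrix(0, ng, ng)
  ndir <- 0
  for (r in seq_len(nrow(dirs))) {
    cnt <- matrix(0, ng, ng)
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        a <- lev[i, j, k]
        if (is.na(a)) next
        ii <- i + dirs[r, 1]; jj <- j + dirs[r, 2]; kk <- k + dirs[r, 3]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3]) next
        b <- lev[ii, jj, kk]
        if (is.na(b)) next
        cnt[a, b] <- cnt[a, b] + 1
        cnt[b, a] <- cnt[b, a] + 1
      }
    if (sum(cnt) > 0) {
      acc <- acc + cnt / sum(cnt)
      ndir <- ndir + 1
    }
  }
  acc / ndir
}

oracle_glcm_features <- function(lev, ng = max(lev, na.rm = TRUE)) {
  p <- oracle_glcm_matrix(lev)
  con <- cor_num <- id <- nid <- en <- ent <- 0
  pi_ <- rowSums(p)
  mu <- sum(seq_len(ng) * pi_)
  s2 <- sum((seq_len(ng) - mu)^2 * pi_)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    con <- con + (i - j)^2 * p[i, j]
    cor_num <- cor_num + (i - mu) * (j - mu) * p[i, j]
    id <- id + p[i, j] / (1 + abs(i - j))
    nid <- nid + p[i, j] / (1 + abs(i - j) / ng)
    en <- en + p[i, j]^2
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
  }
  list(contrast = con, correlation = if (s2 == 0) 1 else cor_num / s2,
       inverse_difference = id, normalized_inverse_difference = nid,
       joint_energy = en, joint_entropy = ent)
}

oracle_ngtdm_features <- function(lev, ng = max(lev, na.rm = TRUE)) {
  d <- dim(lev)
  li <- c(); devs <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (k in seq_len(d[3])) {
      a <- lev[i, j, k]
      if (is.na(a)) next
      nb <- c()
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3]) next
        b <- lev[ii, jj, kk]
        if (!is.na(b)) nb <- c(nb, b)
      }
      if (!length(nb)) next
      li <- c(li, a)
      devs <- c(devs, abs(a - mean(nb)))
    }
  N <- length(li)
  n_i <- tabulate(li, nbins = ng)
  s_i <- sapply(seq_len(ng), function(g) sum(devs[li == g]))
  p_i <- n_i / N
  pres <- which(p_i > 0)
  ngp <- length(pres)
  ps <- sum(p_i * s_i)
  bus_den <- 0; cmplx <- 0; strg <- 0; con_sum <- 0
  for (i in pres) for (j in pres) {
    if (i != j) {
      bus_den <- bus_den + abs(i * p_i[i] - j * p_i[j])
      cmplx <- cmplx + abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
        (p_i[i] + p_i[j])
      strg <- strg + (p_i[i] + p_i[j]) * (i - j)^2
    }
    con_sum <- con_sum + p_i[i] * p_i[j] * (i - j)^2
  }
  list(
    busyness = if (bus_den == 0) 0 else ps / bus_den,
    coarseness = if (ps == 0) 1e6 else min(1 / ps, 1e6),
    complexity = cmplx / N,
    contrast = if (ngp <= 1) 0 else
      (con_sum / (ngp * (ngp - 1))) * (sum(s_i) / N),
    strength = if (sum(s_i) == 0) 0 else strg / sum(s_i))
}

# exact two-sided signed-rank p by full 2^n enumeration (midranks kept)
oracle_wilcoxon_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  sg <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- sg %*% r
  min(1, 2 * min(mean(Wall <= W + 1e-9), mean(Wall >= W - 1e-9)))
}
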