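# Brute-force oracles shipped with the package (inst/oracle), shared by
# the tests and the acceptance script, plus small ROI fixtures.

source(system.file("oracle", "texture_oracle.R", package = "dualPET"),
       local = TRUE)

# random discretized ROI fixture: cuboid grid, every voxel in-mask with
# probability p_mask, levels uniform on 1..ng
random_disc <- function(dims, ng, seed, p_mask = 1) {
  set.seed(seed)
  msk <- array(runif(prod(dims)) <= p_mask, dims)
  if (!any(msk)) msk[1, 1, 1] <- TRUE
  lev <- array(NA_integer_, dims)
  lev[msk] <- sample.int(ng, sum(msk), replace = TRUE)
  make_disc(lev)
}

make_disc <- function(lev, w = 0.5, spacing = 1) {
  msk <- voiMask(!is.na(lev), spacing)
  new("DiscretizedVolume", levels = lev, binWidth = w,
      nLevels = max(lev, na.rm = TRUE), mask = msk)
}
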