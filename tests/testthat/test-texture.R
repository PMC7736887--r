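# First-order, GLCM and NGTDM features vs hand values and brute force.

test_that("intensity moments match the hand-computed example", {
  a <- array(c(1, 1, 1, 3), c(4, 1, 1))
  img <- uptakeVolume(a, 2, unit = "SUV")
  m <- voiMask(array(TRUE, dim(a)), 2)
  disc <- discretizeFBW(img, m)
  f <- intensityFeatures(img, m, disc)
  expect_equal(f$standard_deviation, sqrt(0.75), tolerance = 1e-12)
  expect_equal(f$skewness, 1.1547, tolerance = 1e-4)
  expect_equal(f$kurtosis, 2.3333, tolerance = 1e-4)
})

test_that("constant ROI: entropy 0, uniformity 1, SD 0, flagged", {
  img <- uptakeVolume(array(2, c(3, 3, 3)), 2, unit = "SUV")
  m <- voiMask(array(TRUE, c(3, 3, 3)), 2)
  f <- intensityFeatures(img, m, discretizeFBW(img, m))
  expect_equal(f$entropy, 0)
  expect_equal(f$uniformity, 1)
  expect_equal(f$standard_deviation, 0)
  expect_equal(f$skewness, 0)
  expect_true(f$degenerate)
})

test_that("two equiprobable levels give 1 bit entropy, uniformity 0.5", {
  a <- array(c(0.2, 0.2, 0.7, 0.7), c(4, 1, 1))
  img <- uptakeVolume(a, 2, unit = "SUV")
  m <- voiMask(array(TRUE, dim(a)), 2)
  f <- intensityFeatures(img, m, discretizeFBW(img, m))
  expect_equal(f$entropy, 1, tolerance = 1e-12)
  expect_equal(f$uniformity, 0.5, tolerance = 1e-12)
})

test_that("GLCM features match the 1x1x4 hand example", {
  lev <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  g <- glcmFeatures(make_disc(lev))
  expect_equal(g$contrast, 1 / 3, tolerance = 1e-10)
  expect_equal(g$correlation, 1 / 3, tolerance = 1e-10)
  expect_equal(g$joint_energy, 10 / 36, tolerance = 1e-10)
  expect_equal(g$joint_entropy, 1.9183, tolerance = 1e-4)
  expect_equal(g$normalized_inverse_difference, 8 / 9, tolerance = 1e-10)
})

test_that("constant ROI GLCM is the degenerate single-cell matrix", {
  lev <- array(3L, c(3, 3, 3))
  g <- glcmFeatures(make_disc(lev))
  expect_equal(g$contrast, 0)
  expect_equal(g$joint_entropy, 0)
  expect_equal(g$joint_energy, 1)
  expect_equal(g$inverse_difference, 1)
  expect_equal(g$normalized_inverse_difference, 1)
  expect_equal(g$correlation, 1)
  expect_true(g$degenerate)
})

test_that("averaged GLCM sums to 1 and is symmetric", {
  for (s in 1:5) {
    disc <- random_disc(c(5, 5, 5), ng = 4, seed = s, p_mask = 0.7)
    p <- dualPET:::glcm_matrix(disc)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_lt(max(abs(p - t(p))), 1e-12)
  }
})

test_that("GLCM features match brute-force enumeration on random ROIs", {
  for (s in 1:10) {
    disc <- random_disc(c(5, 6, 5), ng = 5, seed = 100 + s, p_mask = 0.8)
    got <- glcmFeatures(disc)
    want <- oracle_glcm_features(voxelData(disc), ng = disc@nLevels)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10,
                   label = sprintf("glcm %s (seed %d)", nm, s))
  }
})

test_that("NGTDM features match the 1x1x4 hand example", {
  lev <- array(c(1L, 1L, 1L, 2L), c(1, 1, 4))
  f <- ngtdmFeatures(make_disc(lev))
  expect_equal(f$coarseness, 1.6, tolerance = 1e-10)
  expect_equal(f$busyness, 1.25, tolerance = 1e-10)
  expect_equal(f$strength, 4 / 3, tolerance = 1e-10)
  expect_equal(f$complexity, 0.3125, tolerance = 1e-10)
})

test_that("constant ROI NGTDM: contrast 0, complexity 0, capped coarseness", {
  lev <- array(2L, c(3, 3, 3))
  f <- ngtdmFeatures(make_disc(lev))
  expect_equal(f$contrast, 0)
  expect_equal(f$complexity, 0)
  expect_equal(f$coarseness, 1e6)
})

test_that("voxels without in-mask neighbors are excluded from N", {
  lev <- array(NA_integer_, c(7, 1, 1))
  lev[1:3] <- c(1L, 2L, 1L)
  lev[7] <- 5L  # isolated
  f_with <- ngtdmFeatures(make_disc(lev))
  lev2 <- lev; lev2[7] <- NA_integer_
  f_without <- ngtdmFeatures(make_disc(lev2))
  for (nm in names(f_with))
    expect_equal(f_with[[nm]], f_without[[nm]], tolerance = 1e-12)
})

test_that("NGTDM features match brute-force enumeration on random ROIs", {
  for (s in 1:10) {
    disc <- random_disc(c(5, 5, 5), ng = 5, seed = 200 + s, p_mask = 0.8)
    got <- ngtdmFeatures(disc)
    want <- oracle_ngtdm_features(voxelData(disc), ng = disc@nLevels)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10,
                   label = sprintf("ngtdm %s (seed %d)", nm, s))
  }
})
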