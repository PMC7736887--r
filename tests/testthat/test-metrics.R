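# SUL_peak, MTV/TLG and combined uptake metrics.

test_that("SUL_peak of a constant field is the constant", {
  img <- uptakeVolume(array(4.2, c(8, 8, 8)), 2, unit = "SUL")
  m <- voiMask(array(TRUE, c(8, 8, 8)), 2)
  expect_equal(sulPeak(img, m), 4.2, tolerance = 1e-12)
})

test_that("single hot voxel on a 4 mm grid averages over 19 kernel voxels", {
  a <- array(0, c(9, 9, 9))
  a[5, 5, 5] <- 19
  img <- uptakeVolume(a, 4, unit = "SUL")
  mk <- array(FALSE, c(9, 9, 9)); mk[5, 5, 5] <- TRUE
  expect_equal(sulPeak(img, voiMask(mk, 4)), 1.0, tolerance = 1e-12)
})

test_that("kernel truncation at the image boundary uses in-grid voxels only", {
  a <- array(1, c(3, 9, 9))  # corner-adjacent mask voxel
  img <- uptakeVolume(a, 4, unit = "SUL")
  mk <- array(FALSE, dim(a)); mk[1, 1, 1] <- TRUE
  expect_equal(sulPeak(img, voiMask(mk, 4)), 1.0, tolerance = 1e-12)
})

test_that("MTV/TLG match the hand-computed bimodal example", {
  a <- array(0, c(10, 1, 1))
  a[] <- c(rep(0.5, 5), rep(3.5, 5))
  img <- uptakeVolume(a, 2, unit = "SUV")
  m <- voiMask(array(TRUE, dim(a)), 2)
  mv <- metabolicVolume(img, m)
  # VOI mean 2.0, cut 0.8 -> 5 voxels of 8 mm^3
  expect_equal(mv$MTV_mL, 0.04, tolerance = 1e-12)
  expect_equal(mv$TLG, 0.14, tolerance = 1e-12)
})

test_that("uniform VOI gives MTV = VOI volume and TLG = MTV x value", {
  img <- uptakeVolume(array(5, c(4, 4, 4)), 2, unit = "SUV")
  m <- voiMask(array(TRUE, c(4, 4, 4)), 2)
  mv <- metabolicVolume(img, m)
  expect_equal(mv$MTV_mL, 64 * 8 / 1000, tolerance = 1e-12)
  expect_equal(mv$TLG, mv$MTV_mL * 5, tolerance = 1e-12)
})

test_that("MTV never exceeds the VOI volume and VOI-mean TLG is selectable", {
  set.seed(3)
  img <- uptakeVolume(array(runif(125, 0, 10), c(5, 5, 5)), 2,
                      unit = "SUV")
  m <- voiMask(array(runif(125) < 0.6, c(5, 5, 5)), 2)
  mv <- metabolicVolume(img, m)
  expect_lte(mv$MTV_mL, sum(voxelData(m)) * 8 / 1000 + 1e-12)
  mv2 <- metabolicVolume(img, m, tlg_mean = "voi")
  expect_equal(mv2$TLG, mv2$MTV_mL * mean(voxelData(img)[voxelData(m)]),
               tolerance = 1e-12)
})

test_that("uptake metrics on constants give TBR 2 and respect bounds", {
  a <- array(2, c(10, 10, 10)); a[3:5, 3:5, 3:5] <- 4
  sul <- uptakeVolume(a, 4, unit = "SUL", modality = "db")
  suv <- uptakeVolume(a, 4, unit = "SUV", modality = "db")
  tum <- voiMask(array(seq_len(1000) %in%
                         which(a == 4), c(10, 10, 10)), 4)
  bgm <- array(FALSE, c(10, 10, 10)); bgm[8:9, 8:9, 8:9] <- TRUE
  bg <- voiMask(bgm, 4, role = "background-contralateral")
  met <- uptakeMetrics(sul, suv, tum, list(contralateral = bg), d_MRI = 2)
  # kernel extends into the 2-background, so SUL_peak < SUL_max here
  expect_lte(met$SUL_peak, met$SUL_max)
  expect_lte(met$SUL_mean, met$SUL_max)
  expect_equal(met$TBR_contralateral, met$SUL_peak / 2, tolerance = 1e-12)
  expect_true(is.na(met$TBR_liver))  # db: no liver background
  expect_named(met, c("SUL_max", "SUL_mean", "SUL_peak", "MTV_mL", "TLG",
                      "TBR_liver", "TBR_contralateral", "d_MRI_cm"))
})

test_that("a single hot voxel can push SUL_peak below SUL_mean", {
  a <- array(0, c(9, 9, 9))
  a[5, 5, 5] <- 100
  sul <- uptakeVolume(a, 4, unit = "SUL", modality = "wb")
  suv <- uptakeVolume(a + 3, 4, unit = "SUV", modality = "wb")
  mk <- array(FALSE, dim(a)); mk[5, 5, 5] <- TRUE
  tum <- voiMask(mk, 4)
  met <- uptakeMetrics(sul, suv, tum, d_MRI = 1)
  expect_lt(met$SUL_peak, met$SUL_mean)  # mean over 1 voxel = 100
  expect_lte(met$SUL_peak, met$SUL_max)
})

test_that("non-positive background means give NA ratios, not infinities", {
  a <- array(1, c(6, 6, 6))
  sul <- uptakeVolume(a, 4, unit = "SUL", modality = "wb")
  suv <- uptakeVolume(a, 4, unit = "SUV", modality = "wb")
  tum <- voiMask(array(TRUE, dim(a)), 4)
  bgm <- array(FALSE, dim(a)); bgm[1, 1, 1] <- TRUE
  sul@data[1, 1, 1] <- 0
  bg <- voiMask(bgm, 4, role = "background-liver")
  met <- uptakeMetrics(sul, suv, tum, list(liver = bg), d_MRI = 1)
  expect_true(is.na(met$TBR_liver))
})
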