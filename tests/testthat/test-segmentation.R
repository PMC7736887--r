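# Tumor segmentation and background VOIs.

row_image <- function(vals, modality = "wb") {
  uptakeVolume(array(vals, c(length(vals), 1, 1)), 4, unit = "SUV",
               modality = modality)
}

test_that("modality selects the threshold: db 3.0, wb 2.5", {
  expect_equal(segmentationThreshold("db"), 3.0)
  expect_equal(segmentationThreshold("wb"), 2.5)
  img <- row_image(c(0, 2.6, 2.4, 2.6, 0))
  # wb: 2.6 passes; db: nothing does
  expect_s4_class(segmentTumor(img, "wb", c(2, 1, 1)), "VoiMask")
  expect_error(segmentTumor(img, "db", c(2, 1, 1)), "no voxels")
  # a sub-threshold seed with a non-empty supra set is its own error
  img2 <- row_image(c(0, 2.6, 2.4, 3.6, 0))
  expect_error(segmentTumor(img2, "db", c(2, 1, 1)), "below")
  expect_s4_class(segmentTumor(img2, "db", c(4, 1, 1)), "VoiMask")
})

test_that("sub-threshold gaps break connectivity", {
  img <- row_image(c(0, 2.6, 2.4, 2.6, 0))
  m <- segmentTumor(img, "wb", c(2, 1, 1))
  expect_identical(which(voxelData(m)), 2L)
})

test_that("a uniformly supra-threshold image segments whole", {
  img <- uptakeVolume(array(10, c(4, 4, 4)), 2, unit = "SUV")
  m <- segmentTumor(img, "wb", c(3, 2, 1))
  expect_true(all(voxelData(m)))
})

test_that("segmentation uses 26-connectivity", {
  a <- array(0, c(3, 3, 3))
  a[1, 1, 1] <- 5; a[2, 2, 2] <- 5  # diagonal neighbors
  img <- uptakeVolume(a, 1, unit = "SUV")
  m <- segmentTumor(img, "wb", c(1, 1, 1))
  expect_equal(sum(voxelData(m)), 2L)
})

test_that("segmentation is idempotent under reseeding inside its output", {
  set.seed(11)
  a <- array(runif(6^3, 0, 6), c(6, 6, 6))
  img <- uptakeVolume(a, 1, unit = "SUV")
  seed0 <- which(a >= 2.5, arr.ind = TRUE)[1, ]
  m1 <- segmentTumor(img, "wb", seed0)
  inside <- arrayInd(which(voxelData(m1)), dim(a))
  for (r in c(1, nrow(inside))) {
    m2 <- segmentTumor(img, "wb", inside[r, ])
    expect_identical(voxelData(m2), voxelData(m1))
  }
})

test_that("1.2 cm sphere on a 4 mm grid covers 19 voxel centers", {
  # offsets with |v| <= 6 mm: 1 center + 6 faces + 12 edge-diagonals
  # (at sqrt(2)*4 = 5.66 mm)
  img <- uptakeVolume(array(1, c(9, 9, 9)), 4, unit = "SUV",
                      modality = "wb")
  m <- backgroundVoi(img, "liver", center = c(5, 5, 5))
  expect_equal(sum(voxelData(m)), 19L)
  expect_identical(maskRole(m), "background-liver")
})

test_that("cylinder VOI equals the brute-force lattice count on a 1 mm grid", {
  img <- uptakeVolume(array(1, c(21, 21, 21)), 1, unit = "SUV",
                      modality = "db")
  m <- backgroundVoi(img, "contralateral", center = c(11, 11, 11))
  g <- expand.grid(-10:10, -10:10, -10:10)
  want <- sum(g[, 1]^2 + g[, 2]^2 <= 36 & abs(g[, 3]) <= 6)
  expect_equal(sum(voxelData(m)), want)
  expect_identical(maskRole(m), "background-contralateral")
})

test_that("boundary clipping warns with the clipped fraction", {
  img <- uptakeVolume(array(1, c(9, 9, 9)), 4, unit = "SUV",
                      modality = "wb")
  expect_warning(m <- backgroundVoi(img, "liver", center = c(1, 5, 5)),
                 "clipped")
  expect_lt(sum(voxelData(m)), 19L)
  expect_error(backgroundVoi(img, "liver", center = c(10, 5, 5)),
               "inside the image")
})

test_that("contralateral centroid lands in the non-tumor half", {
  a <- array(0, c(20, 10, 10))
  a[3:6, 4:7, 4:7] <- 5     # "tumor" side, x low
  a[14:17, 4:7, 4:7] <- 1   # contralateral parenchyma
  img <- uptakeVolume(a, 4, unit = "SUV", modality = "wb")
  m <- backgroundVoi(img, "contralateral",
                     center = "contralateral-centroid",
                     exclude = c(4, 5, 5))
  ctr <- colMeans(arrayInd(which(voxelData(m)), dim(a)))
  expect_gt(ctr[1], 10)
})
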