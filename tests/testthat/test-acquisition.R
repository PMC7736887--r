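# Acquisition simulation: blur, voxelization, noise, FOV.

test_that("identity acquisition reproduces the ground-truth grid", {
  ph <- unit_phantom()
  cfg <- acquisitionConfig("wb", spacing = 0.5, fwhm = 0, noiseCoef = 0)
  out <- simulateAcquisition(ph, cfg, seed = 1, output_unit = "SUV")
  expect_identical(voxelData(out), voxelData(ph))
})

test_that("noise-free blur-free acquisition conserves total activity", {
  ph <- unit_phantom()
  cfg <- acquisitionConfig("wb", spacing = 2, fwhm = 0, noiseCoef = 0)
  out <- simulateAcquisition(ph, cfg, seed = 1, output_unit = "SUV")
  tot_in <- sum(voxelData(ph)) * prod(voxelSpacing(ph))
  tot_out <- sum(voxelData(out)) * prod(voxelSpacing(out))
  expect_lt(abs(tot_out - tot_in) / tot_in, 1e-6)
})

test_that("blur never increases the global maximum", {
  ph <- unit_phantom()
  for (fwhm in c(2, 7)) {
    cfg <- acquisitionConfig("wb", spacing = 2, fwhm = fwhm, noiseCoef = 0)
    out <- simulateAcquisition(ph, cfg, seed = 1, output_unit = "SUV")
    expect_lte(max(voxelData(out)), max(voxelData(ph)))
  }
})

test_that("blurred small-sphere center matches the analytic convolution", {
  # 1 cm uniform sphere, 6 mm FWHM, zero background: recovery < 1 and
  # equal to the closed-form Gaussian-sphere convolution at the center
  params <- list(parenchyma_suv_range = c(0, 0), liver_suv_range = c(0, 0))
  spec <- lesionSpec(diameter = 1, baseUptake = 8,
                     heterogeneityAmplitude = 0)
  ph <- buildPhantom(spec, seed = 2, params = params)
  cfg <- acquisitionConfig("wb", spacing = 0.5, fwhm = 6, noiseCoef = 0)
  out <- simulateAcquisition(ph, cfg, seed = 1, output_unit = "SUV")
  ctr <- round(ph@lesion@center / 0.5) + 1
  got <- voxelData(out)[ctr[1], ctr[2], ctr[3]]
  want <- oracle_sphere_center(R = 5, sigma = 6 / 2.3548, A = 8)
  expect_lt(max(voxelData(out)), max(voxelData(ph)))
  expect_lt(abs(got - want) / want, 0.02)
})

test_that("maximum-uptake recovery is non-decreasing in lesion diameter", {
  params <- list(parenchyma_suv_range = c(0, 0), liver_suv_range = c(0, 0))
  rec <- vapply(c(1, 2, 3, 4, 5), function(d_cm) {
    ph <- buildPhantom(lesionSpec(diameter = d_cm, baseUptake = 8,
                                  heterogeneityAmplitude = 0),
                       seed = 3, params = params)
    cfg <- acquisitionConfig("wb", fwhm = 6, noiseCoef = 0)
    out <- simulateAcquisition(ph, cfg, seed = 1, output_unit = "SUV")
    max(voxelData(out)) / max(voxelData(ph))
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
  expect_lt(rec[1], 1)
})

test_that("acquisition noise is seed-deterministic", {
  ph <- unit_phantom()
  cfg <- acquisitionConfig("wb")
  o1 <- simulateAcquisition(ph, cfg, seed = 8)
  o2 <- simulateAcquisition(ph, cfg, seed = 8)
  o3 <- simulateAcquisition(ph, cfg, seed = 9)
  expect_identical(voxelData(o1), voxelData(o2))
  expect_false(identical(voxelData(o1), voxelData(o3)))
})

test_that("breast FOV drops the liver; whole-body FOV keeps it", {
  ph <- unit_phantom()
  db <- simulateAcquisition(ph, acquisitionConfig("db", noiseCoef = 0),
                            seed = 1, output_unit = "SUV")
  wb <- simulateAcquisition(ph, acquisitionConfig("wb", noiseCoef = 0),
                            seed = 1, output_unit = "SUV")
  geo <- phantomGeometry()
  # the db grid ends before the liver region begins
  db_zmax <- (dim(voxelData(db))[3] - 1) * voxelSpacing(db)[3]
  expect_lt(db_zmax, geo$liver_center[3] - geo$liver_radius)
  # liver uptake visible in wb
  liv_idx <- round(geo$liver_center / 4) + 1
  expect_gt(voxelData(wb)[liv_idx[1], liv_idx[2], liv_idx[3]], 1)
})

test_that("a FOV excluding the lesion is rejected by name", {
  geo <- phantomGeometry()
  spec <- lesionSpec(center = geo$liver_center, diameter = 1)
  # lesion placed outside the breast is rejected at build time already;
  # so fake it by moving the breast FOV limit instead
  ph <- unit_phantom()
  ph2 <- ph
  ph2@params$geometry$breast_fov_zmax <- 10
  expect_error(
    simulateAcquisition(ph2, acquisitionConfig("db"), seed = 1),
    "excludes the lesion")
})

test_that("non-integer or finer output spacing is rejected", {
  ph <- unit_phantom()
  expect_error(simulateAcquisition(
    ph, acquisitionConfig("db", spacing = 0.75), seed = 1),
    "integer multiple")
  expect_error(simulateAcquisition(
    ph, acquisitionConfig("db", spacing = 0.25), seed = 1),
    ">= phantom spacing")
})
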