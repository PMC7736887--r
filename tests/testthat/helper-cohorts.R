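# Shared simulated cohorts, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# default-condition paired cohort used for the partial-volume checks
pve_cohort <- function() {
  if (is.null(.fixture_cache$pve))
    .fixture_cache$pve <- generateCohort(20, seed = 42)
  .fixture_cache$pve
}

# noise-free cohort for volumetric accuracy checks
noise_free_cohort <- function() {
  if (is.null(.fixture_cache$nf))
    .fixture_cache$nf <- generateCohort(
      5, seed = 7,
      db_config = acquisitionConfig("db", noiseCoef = 0),
      wb_config = acquisitionConfig("wb", noiseCoef = 0),
      diameter_range = c(2.0, 5.2))
  .fixture_cache$nf
}

# small shared phantom (2 cm uniform lesion, no heterogeneity)
unit_phantom <- function() {
  if (is.null(.fixture_cache$ph))
    .fixture_cache$ph <- buildPhantom(
      lesionSpec(diameter = 2, heterogeneityAmplitude = 0), seed = 101)
  .fixture_cache$ph
}

# metrics-only quantification of one simulated case on one modality
quantify_metrics <- function(case, modality) {
  vol <- case[[modality]]
  at <- case$attrs[[modality]]
  suv <- computeSUV(vol, at, decayParams(interval = at@uptakeTime))
  sul <- suvToSUL(suv, at)
  seed <- dualPET:::lesion_seed_index(suv, case$truth$lesion_center)
  tumor <- segmentTumor(suv, modality, seed)
  mv <- metabolicVolume(suv, tumor)
  data.frame(
    case = case$id, modality = modality,
    SUL_max = max(voxelData(sul)[voxelData(tumor)]),
    SUL_mean = mean(voxelData(sul)[voxelData(tumor)]),
    SUL_peak = sulPeak(sul, tumor),
    MTV_mL = mv$MTV_mL, TLG = mv$TLG,
    d_MRI_cm = case$truth$d_MRI_cm)
}
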