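# Image-domain acquisition model: PSF blur -> voxelization -> noise -> FOV.

#' Simulate a PET acquisition of a phantom
#'
#' Image-domain abstraction of a reconstructed PET acquisition:
#' the ground-truth field is convolved with an isotropic Gaussian point
#' spread (FWHM in mm), block-averaged onto the output voxel grid
#' (preserving total activity), degraded with additive heteroscedastic
#' Gaussian noise (sd = noiseCoef * sqrt(local signal), on the SUV
#' scale), and cropped to the configured field of view. The breast FOV
#' covers both breasts; the whole-body FOV adds the liver.
#'
#' @param phantom An \linkS4class{ActivityPhantom}.
#' @param config An \linkS4class{AcquisitionConfig}; its spacing must be
#'   an integer multiple of the phantom's fine spacing.
#' @param seed Integer seed for the noise draw.
#' @param output_unit "Bq/mL" (default; the SUV-scale ground truth is
#'   scaled by decayed dose over body weight for the modality's
#'   attributes) or "SUV" to keep the simulated image on the SUV scale.
#' @return An \linkS4class{UptakeVolume} tagged with the config modality.
#' @examples
#' ph <- buildPhantom(lesionSpec(diameter = 2), seed = 1)
#' v <- simulateAcquisition(ph, acquisitionConfig("wb"), seed = 2)
#' v
#' @export
simulateAcquisition <- function(phantom, config, seed,
                                output_unit = c("Bq/mL", "SUV")) {
  stopifnot(is(phantom, "ActivityPhantom"), is(config, "AcquisitionConfig"))
  output_unit <- match.arg(output_unit)
  sp <- phantom@spacing[1]
  if (config@spacing < sp - 1e-9)
    stop("config spacing must be >= phantom spacing", call. = FALSE)
  fac <- config@spacing / sp
  if (abs(fac - round(fac)) > 1e-9)
    stop("config spacing must be an integer multiple of the phantom spacing",
         call. = FALSE)
  fac <- as.integer(round(fac))
  geo <- phantom@params$geometry
  if (is.null(geo)) geo <- phantomGeometry()

  if (config@fov == "breast" &&
      phantom@lesion@center[3] >= geo$breast_fov_zmax)
    stop(sprintf(
      "breast FOV (z < %g mm) excludes the lesion at z = %g mm",
      geo$breast_fov_zmax, phantom@lesion@center[3]), call. = FALSE)

  img <- gaussian_blur3d(phantom@activity, config@fwhm, phantom@spacing)
  if (fac > 1L) img <- block_average(img, rep(fac, 3L))
  out_sp <- rep(config@spacing, 3)

  if (config@fov == "breast") {
    # keep output voxels whose centers lie below the breast FOV limit
    zc <- (seq_len(dim(img)[3]) - 1) * out_sp[3]
    img <- img[, , zc < geo$breast_fov_zmax, drop = FALSE]
  }

  if (config@noiseCoef > 0) {
    img <- with_seed(seed, {
      img + rnorm(length(img),
                  sd = config@noiseCoef * sqrt(pmax(img, 0))) |>
        array(dim(img))
    })
  }

  if (output_unit == "Bq/mL") {
    at <- phantom@attrs[[config@modality]]
    img <- img * suv_unit_concentration(at)
  }
  uptakeVolume(img, spacing = out_sp, origin = phantom@origin,
               unit = output_unit, modality = config@modality)
}

# Activity concentration (Bq/mL) corresponding to SUV = 1 at scan time:
# decayed dose (Bq) / body weight (g), assuming tissue density 1 g/mL.
suv_unit_concentration <- function(attrs, half_life_min = 109.77) {
  dose_bq <- attrs@injectedDose * 1e6 *
    2^(-attrs@uptakeTime / half_life_min)
  dose_bq / (attrs@bodyWeight * 1000)
}
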