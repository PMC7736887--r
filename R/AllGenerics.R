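# Accessor generics and show methods.

#' @describeIn uptakeVolume Voxel data array accessor.
#' @param x An object with voxel data.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @describeIn uptakeVolume Voxel spacing (mm per axis).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @describeIn uptakeVolume Grid origin (mm).
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @describeIn uptakeVolume Unit tag ("Bq/mL", "SUV", "SUL").
#' @export
setGeneric("imageUnit", function(x) standardGeneric("imageUnit"))
#' @describeIn uptakeVolume Modality tag ("db", "wb", "none").
#' @export
setGeneric("imageModality", function(x) standardGeneric("imageModality"))

#' Mask role accessor
#' @param x A \linkS4class{VoiMask}.
#' @return The role tag.
#' @export
setGeneric("maskRole", function(x) standardGeneric("maskRole"))

#' Voxel volume in mL
#' @param x An object with a voxel grid.
#' @return Single voxel volume in mL.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @export
setMethod("voxelData", "UptakeVolume", function(x) x@data)
#' @export
setMethod("voxelData", "VoiMask", function(x) x@data)
#' @export
setMethod("voxelData", "ActivityPhantom", function(x) x@activity)
#' @export
setMethod("voxelData", "DiscretizedVolume", function(x) x@levels)
#' @export
setMethod("voxelSpacing", "UptakeVolume", function(x) x@spacing)
#' @export
setMethod("voxelSpacing", "VoiMask", function(x) x@spacing)
#' @export
setMethod("voxelSpacing", "ActivityPhantom", function(x) x@spacing)
#' @export
setMethod("voxelOrigin", "UptakeVolume", function(x) x@origin)
#' @export
setMethod("voxelOrigin", "VoiMask", function(x) x@origin)
#' @export
setMethod("voxelOrigin", "ActivityPhantom", function(x) x@origin)
#' @export
setMethod("imageUnit", "UptakeVolume", function(x) x@unit)
#' @export
setMethod("imageModality", "UptakeVolume", function(x) x@modality)
#' @export
setMethod("maskRole", "VoiMask", function(x) x@role)
#' @export
setMethod("voxelVolume", "UptakeVolume",
          function(x) prod(x@spacing) / 1000)
#' @export
setMethod("voxelVolume", "VoiMask",
          function(x) prod(x@spacing) / 1000)

setMethod("show", "UptakeVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "UptakeVolume [%s, %s]: %d x %d x %d voxels @ %s mm\n",
    object@unit, object@modality, d[1], d[2], d[3],
    paste(format(object@spacing, trim = TRUE), collapse = " x ")))
  cat(sprintf("  range: %.4g .. %.4g\n",
              min(object@data), max(object@data)))
})

setMethod("show", "VoiMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoiMask [%s]: %d/%d voxels, %.3f mL\n", object@role,
              sum(object@data), prod(d),
              sum(object@data) * prod(object@spacing) / 1000))
})

setMethod("show", "ActivityPhantom", function(object) {
  d <- dim(object@activity)
  cat(sprintf(
    "ActivityPhantom: %d x %d x %d @ %.2g mm, lesion d = %.2f cm (seed %d)\n",
    d[1], d[2], d[3], object@spacing[1], object@lesion@diameter,
    object@seed))
})

setMethod("show", "PatientAttributes", function(object) {
  cat(sprintf(
    "PatientAttributes: sex %s, %.1f kg, %.2f m, %.1f MBq, t = %.0f min\n",
    object@sex, object@bodyWeight, object@height, object@injectedDose,
    object@uptakeTime))
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf(
    "AcquisitionConfig [%s]: %.3g mm voxels, FWHM %.3g mm, noise %.3g, FOV %s\n",
    object@modality, object@spacing, object@fwhm, object@noiseCoef,
    object@fov))
})

setMethod("show", "DiscretizedVolume", function(object) {
  cat(sprintf("DiscretizedVolume: w = %.3g, N_g = %d, %d in-mask voxels\n",
              object@binWidth, object@nLevels, sum(object@mask@data)))
})
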