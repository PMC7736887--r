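# S4 classes for volumetric uptake data and simulation inputs.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' UptakeVolume: a 3D scalar field on a regular grid
#'
#' Holds one volumetric PET image (activity concentration, SUV or SUL)
#' together with its voxel spacing (mm per axis), origin (mm) and a unit
#' and modality tag.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot spacing Numeric length-3, mm per axis; all positive.
#' @slot origin Numeric length-3, mm position of the first voxel center.
#' @slot unit One of \code{"Bq/mL"}, \code{"SUV"}, \code{"SUL"}.
#' @slot modality One of \code{"db"} (dedicated-breast) or \code{"wb"}
#'   (whole-body), or \code{"none"} for modality-agnostic volumes.
#' @export
setClass("UptakeVolume", representation(
  data = "array", spacing = "numeric", origin = "numeric",
  unit = "character", modality = "character"))

setValidity("UptakeVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (!object@unit %in% c("Bq/mL", "SUV", "SUL"))
    msg <- c(msg, "unit must be one of 'Bq/mL', 'SUV', 'SUL'")
  if (!object@modality %in% c("db", "wb", "none"))
    msg <- c(msg, "modality must be 'db', 'wb' or 'none'")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "voxel values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an UptakeVolume
#'
#' @param data 3D numeric array.
#' @param spacing Voxel spacing in mm (length 1 or 3).
#' @param origin Origin in mm (default c(0,0,0)).
#' @param unit Unit tag: "Bq/mL", "SUV" or "SUL".
#' @param modality "db", "wb" or "none".
#' @return An \linkS4class{UptakeVolume}.
#' @examples
#' v <- uptakeVolume(array(1, c(4, 4, 4)), spacing = 2, unit = "SUV")
#' voxelSpacing(v)
#' @export
uptakeVolume <- function(data, spacing, origin = c(0, 0, 0),
                         unit = "Bq/mL", modality = "none") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("UptakeVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), unit = unit, modality = modality)
}

#' VoiMask: a binary volume of interest aligned to an UptakeVolume grid
#'
#' @slot data 3D logical array.
#' @slot spacing,origin Grid geometry, as in \linkS4class{UptakeVolume}.
#' @slot role One of \code{"tumor"}, \code{"background-liver"},
#'   \code{"background-contralateral"}.
#' @export
setClass("VoiMask", representation(
  data = "array", spacing = "numeric", origin = "numeric",
  role = "character"))

setValidity("VoiMask", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L || !is.logical(object@data))
    msg <- c(msg, "data must be a 3D logical array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (!object@role %in% c("tumor", "background-liver",
                          "background-contralateral"))
    msg <- c(msg, "unknown mask role")
  if (length(msg)) msg else TRUE
})

#' Construct a VoiMask
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param spacing Voxel spacing in mm (length 1 or 3).
#' @param origin Origin in mm.
#' @param role Mask role tag.
#' @return A \linkS4class{VoiMask}.
#' @export
voiMask <- function(data, spacing, origin = c(0, 0, 0), role = "tumor") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "logical"
  new("VoiMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), role = role)
}

#' PatientAttributes: per-patient scan attributes
#'
#' @slot sex "F" or "M" (the study cohort is all female).
#' @slot bodyWeight kg.
#' @slot height m.
#' @slot injectedDose MBq.
#' @slot uptakeTime min between injection and scan.
#' @slot bloodGlucose mg/dL (informational).
#' @export
setClass("PatientAttributes", representation(
  sex = "character", bodyWeight = "numeric", height = "numeric",
  injectedDose = "numeric", uptakeTime = "numeric",
  bloodGlucose = "numericOrNULL"))

setValidity("PatientAttributes", function(object) {
  msg <- character(0)
  if (!object@sex %in% c("F", "M")) msg <- c(msg, "sex must be 'F' or 'M'")
  if (object@bodyWeight <= 0) msg <- c(msg, "bodyWeight must be > 0")
  if (object@height <= 0) msg <- c(msg, "height must be > 0")
  if (object@injectedDose <= 0) msg <- c(msg, "injectedDose must be > 0")
  if (object@uptakeTime < 0) msg <- c(msg, "uptakeTime must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct PatientAttributes
#'
#' @param sex "F" or "M".
#' @param bodyWeight Body weight in kg.
#' @param height Height in m.
#' @param injectedDose Injected dose in MBq.
#' @param uptakeTime Uptake time in min.
#' @param bloodGlucose Blood glucose in mg/dL, or NULL.
#' @return A \linkS4class{PatientAttributes}.
#' @export
patientAttributes <- function(sex = "F", bodyWeight, height,
                              injectedDose, uptakeTime = 60,
                              bloodGlucose = NULL) {
  new("PatientAttributes", sex = sex, bodyWeight = bodyWeight,
      height = height, injectedDose = injectedDose,
      uptakeTime = uptakeTime, bloodGlucose = bloodGlucose)
}

#' LesionSpec: geometric and uptake description of one lesion
#'
#' @slot center mm, length-3, in the phantom frame.
#' @slot diameter cm (the longest-diameter scalar carried as d_MRI).
#' @slot baseUptake SUV units; must exceed the parenchyma background.
#' @slot heterogeneityAmplitude Fraction of baseUptake in [0, 1).
#' @slot heterogeneityLength mm correlation length of the intratumoral
#'   uptake field.
#' @export
setClass("LesionSpec", representation(
  center = "numeric", diameter = "numeric", baseUptake = "numeric",
  heterogeneityAmplitude = "numeric", heterogeneityLength = "numeric"))

setValidity("LesionSpec", function(object) {
  msg <- character(0)
  if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
  if (object@diameter <= 0) msg <- c(msg, "diameter must be > 0")
  if (object@baseUptake <= 0) msg <- c(msg, "baseUptake must be > 0")
  if (object@heterogeneityAmplitude < 0 || object@heterogeneityAmplitude >= 1)
    msg <- c(msg, "heterogeneityAmplitude must be in [0, 1)")
  if (object@heterogeneityLength <= 0)
    msg <- c(msg, "heterogeneityLength must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a LesionSpec
#'
#' @param center Lesion center in mm (phantom frame); NULL places the
#'   lesion at the ipsilateral breast center.
#' @param diameter Lesion diameter in cm.
#' @param baseUptake Lesion base uptake in SUV units.
#' @param heterogeneityAmplitude Relative amplitude of the intratumoral
#'   uptake field, in [0, 1).
#' @param heterogeneityLength Correlation length of that field, mm.
#' @return A \linkS4class{LesionSpec}.
#' @export
lesionSpec <- function(center = NULL, diameter, baseUptake = 8,
                       heterogeneityAmplitude = 0.2,
                       heterogeneityLength = 8) {
  if (is.null(center)) center <- phantomGeometry()$breast_ipsi_center
  new("LesionSpec", center = as.numeric(center), diameter = diameter,
      baseUptake = baseUptake,
      heterogeneityAmplitude = heterogeneityAmplitude,
      heterogeneityLength = heterogeneityLength)
}

#' ActivityPhantom: ground-truth digital phantom
#'
#' The ground-truth uptake field (SUV units) on a fine grid, its tissue
#' labels, the lesion record, patient attributes and the seed used.
#'
#' @slot activity 3D numeric array, ground-truth uptake in SUV units.
#' @slot labels 3D integer array: 0 air, 1 parenchyma, 2 lesion, 3 liver,
#'   4 crosstalk hot region.
#' @slot spacing,origin Fine-grid geometry (mm).
#' @slot lesion The \linkS4class{LesionSpec}.
#' @slot attrs A list of per-modality \linkS4class{PatientAttributes}
#'   (elements "db" and "wb").
#' @slot seed Integer RNG seed used to build the phantom.
#' @slot params Named list of the generation parameters actually used.
#' @export
setClass("ActivityPhantom", representation(
  activity = "array", labels = "array", spacing = "numeric",
  origin = "numeric", lesion = "LesionSpec", attrs = "list",
  seed = "integer", params = "list"))

setValidity("ActivityPhantom", function(object) {
  msg <- character(0)
  if (!identical(dim(object@activity), dim(object@labels)))
    msg <- c(msg, "activity and label grids must be congruent")
  if (any(object@activity < 0)) msg <- c(msg, "activity must be >= 0")
  les <- object@activity[object@labels == 2L]
  par <- object@activity[object@labels == 1L]
  if (length(les) && length(par) && mean(les) <= mean(par))
    msg <- c(msg, "lesion mean activity must exceed parenchyma mean")
  if (length(msg)) msg else TRUE
})

#' AcquisitionConfig: an abstracted PET acquisition
#'
#' @slot modality "db" or "wb".
#' @slot spacing Output voxel spacing, mm, isotropic (1 for db, 4 for wb).
#' @slot fwhm Point-spread FWHM in mm (>= 0).
#' @slot noiseCoef Noise coefficient: additive Gaussian noise with
#'   sd = noiseCoef * sqrt(local signal), applied on the SUV scale.
#' @slot fov "breast" (both breasts, no liver) or "wholebody".
#' @export
setClass("AcquisitionConfig", representation(
  modality = "character", spacing = "numeric", fwhm = "numeric",
  noiseCoef = "numeric", fov = "character"))

setValidity("AcquisitionConfig", function(object) {
  msg <- character(0)
  if (!object@modality %in% c("db", "wb")) msg <- c(msg, "bad modality")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  if (object@fwhm < 0) msg <- c(msg, "fwhm must be >= 0")
  if (object@noiseCoef < 0) msg <- c(msg, "noiseCoef must be >= 0")
  if (!object@fov %in% c("breast", "wholebody")) msg <- c(msg, "bad fov")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionConfig
#'
#' Defaults follow the modality: dbPET is reconstructed on a 1 mm grid
#' with a 2 mm FWHM point spread and a breast-only field of view; wbPET
#' on a 4 mm grid with 7 mm FWHM and a whole-body field of view that
#' includes the liver.
#'
#' @param modality "db" or "wb".
#' @param spacing Output voxel spacing in mm; default 1 (db) or 4 (wb).
#' @param fwhm Gaussian PSF FWHM in mm; default 2 (db) or 7 (wb).
#' @param noiseCoef Noise coefficient; default 0.15 (db) or 0.10 (wb).
#' @param fov "breast" or "wholebody"; default by modality.
#' @return An \linkS4class{AcquisitionConfig}.
#' @export
acquisitionConfig <- function(modality = c("db", "wb"), spacing = NULL,
                              fwhm = NULL, noiseCoef = NULL, fov = NULL) {
  modality <- match.arg(modality)
  if (is.null(spacing)) spacing <- if (modality == "db") 1 else 4
  if (is.null(fwhm)) fwhm <- if (modality == "db") 2 else 7
  if (is.null(noiseCoef)) noiseCoef <- if (modality == "db") 0.15 else 0.10
  if (is.null(fov)) fov <- if (modality == "db") "breast" else "wholebody"
  new("AcquisitionConfig", modality = modality, spacing = spacing,
      fwhm = fwhm, noiseCoef = noiseCoef, fov = fov)
}

#' DiscretizedVolume: fixed-bin-width gray levels over a mask
#'
#' Integer gray levels 1..nLevels inside the mask; NA outside.
#'
#' @slot levels 3D integer array (NA outside the mask).
#' @slot binWidth Bin width w in image units (SUV).
#' @slot nLevels N_g, the number of gray levels (max in-mask level).
#' @slot mask The source \linkS4class{VoiMask}.
#' @export
setClass("DiscretizedVolume", representation(
  levels = "array", binWidth = "numeric", nLevels = "integer",
  mask = "VoiMask"))

setValidity("DiscretizedVolume", function(object) {
  msg <- character(0)
  lv <- object@levels[object@mask@data]
  if (length(lv) && (anyNA(lv) || any(lv < 1L) || any(lv > object@nLevels)))
    msg <- c(msg, "in-mask levels must lie in 1..nLevels")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (length(msg)) msg else TRUE
})
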