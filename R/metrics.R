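# PERCIST-style uptake metrics: SUL_peak, MTV, TLG, TBR.

#' SUL_peak: peak kernel-mean uptake
#'
#' For every voxel in the tumor mask, the image is averaged over all
#' image voxels whose centers lie within 0.6 cm (a 1.2 cm-diameter,
#' ~1 mL spherical kernel, the PERCIST convention); the kernel may
#' extend beyond the mask and is truncated at the image boundary.
#' SUL_peak is the maximum of these kernel means.
#'
#' @param image \linkS4class{UptakeVolume} (SUL for PERCIST use).
#' @param tumor \linkS4class{VoiMask}, non-empty, congruent with image.
#' @param kernel_diameter_cm Kernel diameter, cm; default 1.2.
#' @return SUL_peak (same units as the image).
#' @export
sulPeak <- function(image, tumor, kernel_diameter_cm = 1.2) {
  stopifnot(is(image, "UptakeVolume"), is(tumor, "VoiMask"))
  stop_if_not_congruent(image, tumor, "image and tumor mask")
  idx <- which(tumor@data)
  if (!length(idx)) stop("empty tumor mask", call. = FALSE)
  off <- sphere_offsets(kernel_diameter_cm * 10 / 2, image@spacing)
  targets <- arrayInd(idx, dim(tumor@data)) - 1L
  storage.mode(targets) <- "integer"
  means <- kernel_means(image@data, dim(image@data), targets, off)
  max(means)
}

#' Metabolic tumor volume and total lesion glycolysis
#'
#' SUV_mean is first computed over the whole tumor VOI; the MTV region
#' is the subset of VOI voxels with SUV >= 40% of that mean, and MTV is
#' the summed voxel volume of that region. TLG = MTV times SUV_mean,
#' where the mean is taken over the MTV sub-region (default) or over
#' the whole VOI (\code{tlg_mean = "voi"}).
#'
#' @param image \linkS4class{UptakeVolume} in SUV units.
#' @param tumor \linkS4class{VoiMask}, non-empty.
#' @param fraction Relative threshold (default 0.40).
#' @param tlg_mean "mtv" (mean over the MTV sub-region) or "voi".
#' @return List: \code{MTV_mL}, \code{TLG}, \code{mtv_mask}
#'   (\linkS4class{VoiMask} of the MTV sub-region).
#' @export
metabolicVolume <- function(image, tumor, fraction = 0.40,
                            tlg_mean = c("mtv", "voi")) {
  stopifnot(is(image, "UptakeVolume"), is(tumor, "VoiMask"))
  tlg_mean <- match.arg(tlg_mean)
  stop_if_not_congruent(image, tumor, "image and tumor mask")
  vals <- image@data[tumor@data]
  if (!length(vals)) stop("empty tumor mask", call. = FALSE)
  voi_mean <- mean(vals)
  cut <- fraction * voi_mean
  sel <- tumor@data & image@data >= cut
  vv <- prod(image@spacing) / 1000
  mtv <- sum(sel) * vv
  mvals <- image@data[sel]
  tlg <- mtv * if (tlg_mean == "mtv") mean(mvals) else voi_mean
  list(MTV_mL = mtv, TLG = tlg,
       mtv_mask = voiMask(sel, image@spacing, image@origin, role = "tumor"))
}

#' Uptake metrics for one lesion on one modality
#'
#' SUL_max and SUL_mean over the tumor VOI, SUL_peak via
#' \code{\link{sulPeak}}, MTV/TLG via \code{\link{metabolicVolume}} on
#' the SUV image, and tumor-background ratios
#' TBR = SUL_peak(tumor) / SUL_mean(background). The liver TBR is
#' populated only for wb images (the liver lies outside the db field of
#' view). A background with non-positive mean yields an NA ratio.
#'
#' @param sul \linkS4class{UptakeVolume} in SUL units.
#' @param suv \linkS4class{UptakeVolume} in SUV units (same grid).
#' @param tumor Tumor \linkS4class{VoiMask}.
#' @param backgrounds Named list of background \linkS4class{VoiMask}s
#'   ("contralateral", and "liver" for wb).
#' @param d_MRI Longest MRI diameter in cm, carried through.
#' @param fraction MTV threshold fraction (default 0.40).
#' @param tlg_mean TLG mean convention, see \code{\link{metabolicVolume}}.
#' @return One-row data.frame with columns SUL_max, SUL_mean, SUL_peak,
#'   MTV_mL, TLG, TBR_liver, TBR_contralateral, d_MRI_cm.
#' @export
uptakeMetrics <- function(sul, suv, tumor, backgrounds = list(),
                          d_MRI = NA_real_, fraction = 0.40,
                          tlg_mean = c("mtv", "voi")) {
  stopifnot(is(sul, "UptakeVolume"), is(suv, "UptakeVolume"))
  stop_if_not_congruent(sul, tumor, "SUL image and tumor mask")
  stop_if_not_congruent(suv, tumor, "SUV image and tumor mask")
  tvals <- sul@data[tumor@data]
  if (!length(tvals)) stop("empty tumor mask", call. = FALSE)
  peak <- sulPeak(sul, tumor)
  mv <- metabolicVolume(suv, tumor, fraction = fraction,
                        tlg_mean = tlg_mean)
  tbr <- function(region) {
    bg <- backgrounds[[region]]
    if (is.null(bg)) return(NA_real_)
    stop_if_not_congruent(sul, bg, "SUL image and background mask")
    bmean <- mean(sul@data[bg@data])
    if (!is.finite(bmean) || bmean <= 0) return(NA_real_)
    peak / bmean
  }
  tbr_liver <- if (identical(sul@modality, "wb")) tbr("liver") else NA_real_
  data.frame(
    SUL_max = max(tvals), SUL_mean = mean(tvals), SUL_peak = peak,
    MTV_mL = mv$MTV_mL, TLG = mv$TLG, TBR_liver = tbr_liver,
    TBR_contralateral = tbr("contralateral"), d_MRI_cm = d_MRI)
}
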