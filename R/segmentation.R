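# Tumor segmentation and background VOIs.

#' SUV threshold for tumor segmentation, by modality
#'
#' wbPET uses SUV >= 2.5; dbPET uses SUV >= 3.0 (the higher threshold
#' counteracts the higher dbPET background noise).
#'
#' @param modality "db" or "wb".
#' @return The SUV threshold.
#' @export
segmentationThreshold <- function(modality = c("db", "wb")) {
  modality <- match.arg(modality)
  if (modality == "db") 3.0 else 2.5
}

#' Segment the tumor VOI by seeded thresholding
#'
#' The tumor mask is the 26-connected component of the supra-threshold
#' set {SUV >= threshold(modality)} that contains the seed voxel — a
#' seeded-region stand-in for the operator's click in semi-automated
#' segmentation.
#'
#' @param image \linkS4class{UptakeVolume} in SUV units.
#' @param modality "db" or "wb" (default: the image's modality tag);
#'   selects the threshold.
#' @param seed_point Integer length-3 voxel index (1-based) inside the
#'   lesion; must be supra-threshold.
#' @param threshold Optional explicit threshold overriding the modality
#'   default.
#' @return A \linkS4class{VoiMask} with role "tumor".
#' @export
segmentTumor <- function(image, modality = NULL, seed_point,
                         threshold = NULL) {
  stopifnot(is(image, "UptakeVolume"))
  if (image@unit != "SUV")
    stop("segmentTumor expects an image in SUV units", call. = FALSE)
  if (is.null(modality)) modality <- image@modality
  if (is.null(threshold)) threshold <- segmentationThreshold(modality)
  d <- dim(image@data)
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L || any(seed_point < 1L) ||
      any(seed_point > d))
    stop("seed_point must be a voxel index inside the image", call. = FALSE)
  supra <- image@data >= threshold
  if (!any(supra))
    stop(sprintf("no voxels at or above SUV %.2f", threshold),
         call. = FALSE)
  if (!supra[seed_point[1], seed_point[2], seed_point[3]])
    stop(sprintf(
      "seed voxel SUV %.3f is below the segmentation threshold %.2f",
      image@data[seed_point[1], seed_point[2], seed_point[3]], threshold),
      call. = FALSE)
  comp <- connected_component26(supra, seed_point)
  voiMask(comp, image@spacing, image@origin, role = "tumor")
}

#' Background VOI: 1.2 cm sphere or cylinder
#'
#' dbPET: a cylinder of 1.2 cm diameter and 1.2 cm height (axis along
#' the image's third axis) at the contralateral-breast centroid.
#' wbPET: a 1.2 cm-diameter sphere at the given liver or
#' contralateral-breast center. Voxel membership is by voxel-center
#' inclusion.
#'
#' @param image \linkS4class{UptakeVolume}.
#' @param region "contralateral" or "liver".
#' @param center Integer length-3 voxel index, or the string
#'   "contralateral-centroid" to place the VOI at the intensity-weighted
#'   centroid of the half of the image (along axis 1) away from
#'   \code{exclude}.
#' @param shape "sphere" or "cylinder"; default cylinder for db images,
#'   sphere otherwise.
#' @param exclude Optional voxel index (e.g. the tumor seed) identifying
#'   the tumor side when \code{center = "contralateral-centroid"}.
#' @return A \linkS4class{VoiMask} with the matching background role.
#'   If the VOI is clipped by the image boundary a warning reports the
#'   clipped fraction.
#' @export
backgroundVoi <- function(image, region = c("contralateral", "liver"),
                          center, shape = NULL, exclude = NULL) {
  stopifnot(is(image, "UptakeVolume"))
  region <- match.arg(region)
  d <- dim(image@data)
  if (is.character(center) && center == "contralateral-centroid") {
    if (is.null(exclude))
      stop("exclude (tumor-side voxel index) is required for the ",
           "contralateral centroid", call. = FALSE)
    half <- seq_len(d[1]) > d[1] / 2
    if (exclude[1] > d[1] / 2) half <- !half
    sub <- image@data[half, , , drop = FALSE]
    w <- pmax(as.vector(sub), 0)
    if (sum(w) == 0) stop("no signal in the contralateral half",
                          call. = FALSE)
    ijk <- arrayInd(seq_along(sub), dim(sub))
    ctr <- round(colSums(ijk * w) / sum(w))
    ctr[1] <- ctr[1] + if (exclude[1] > d[1] / 2) 0L else
      as.integer(d[1] - dim(sub)[1])
    center <- as.integer(ctr)
  }
  center <- as.integer(center)
  if (length(center) != 3L || any(center < 1L) || any(center > d))
    stop("background VOI center must lie inside the image", call. = FALSE)
  if (is.null(shape))
    shape <- if (image@modality == "db") "cylinder" else "sphere"
  off <- if (shape == "sphere") sphere_offsets(6, image@spacing)
         else cylinder_offsets(6, 6, image@spacing)
  pts <- sweep(off, 2, center, "+")
  inb <- pts[, 1] >= 1L & pts[, 1] <= d[1] &
    pts[, 2] >= 1L & pts[, 2] <= d[2] &
    pts[, 3] >= 1L & pts[, 3] <= d[3]
  if (any(!inb))
    warning(sprintf("background VOI clipped by the image boundary: %.1f%%",
                    100 * mean(!inb)))
  pts <- pts[inb, , drop = FALSE]
  m <- array(FALSE, d)
  m[pts[, 1] + d[1] * (pts[, 2] - 1L) + d[1] * d[2] * (pts[, 3] - 1L)] <- TRUE
  voiMask(m, image@spacing, image@origin,
          role = paste0("background-", region))
}
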