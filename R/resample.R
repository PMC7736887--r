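# Isotropic resampling for radiomics preprocessing.

#' Resample an image and mask to an isotropic grid
#'
#' Trilinear interpolation onto an isotropic grid (default 2 mm)
#' sharing the input origin: db images are down-sampled and wb images
#' up-sampled onto the same spacing so that features are computed at a
#' common resolution. The mask is interpolated as a real-valued field
#' and re-binarized at >= 0.5. Inputs already at the target spacing are
#' returned unchanged.
#'
#' @param image \linkS4class{UptakeVolume}.
#' @param mask \linkS4class{VoiMask} congruent with the image.
#' @param target Target isotropic spacing in mm (default 2).
#' @return List with elements \code{image} and \code{mask}.
#' @export
resampleIsotropic <- function(image, mask, target = 2) {
  stopifnot(is(image, "UptakeVolume"), is(mask, "VoiMask"))
  stop_if_not_congruent(image, mask, "image and mask")
  if (max(abs(image@spacing - target)) < 1e-12)
    return(list(image = image, mask = mask))
  d <- dim(image@data)
  n_new <- pmax(1L, floor((d - 1) * image@spacing / target) + 1L)
  ax <- lapply(1:3, function(a)
    image@origin[a] + (seq_len(n_new[a]) - 1) * target)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  img_new <- array(
    trilinear_interp(image@data, image@spacing, image@origin, pts), n_new)
  msk_real <- array(
    trilinear_interp(array(as.numeric(mask@data), d), image@spacing,
                     image@origin, pts), n_new)
  msk_new <- msk_real >= 0.5
  if (!any(msk_new))
    stop("mask is empty after resampling (lesion too small for the ",
         "target spacing)", call. = FALSE)
  list(
    image = uptakeVolume(img_new, target, image@origin, unit = image@unit,
                         modality = image@modality),
    mask = voiMask(msk_new, target, image@origin, role = mask@role))
}

#' Fixed-bin-width gray-level discretization
#'
#' level(x) = floor(x / w) + 1 with bin edges anchored at zero
#' (half-open bins [k w, (k+1) w)); N_g is the maximum in-mask level,
#' and intermediate levels with zero count are retained in the 1..N_g
#' range for texture-matrix indexing. Anchoring at zero keeps absolute
#' SUV bins comparable across patients and modalities.
#'
#' @param image \linkS4class{UptakeVolume} (SUV or SUL); in-mask values
#'   must be non-negative.
#' @param mask \linkS4class{VoiMask}.
#' @param w Bin width in image units (default 0.5).
#' @return A \linkS4class{DiscretizedVolume}.
#' @export
discretizeFBW <- function(image, mask, w = 0.5) {
  stopifnot(is(image, "UptakeVolume"), is(mask, "VoiMask"))
  stop_if_not_congruent(image, mask, "image and mask")
  if (w <= 0) stop("bin width must be > 0", call. = FALSE)
  vals <- image@data[mask@data]
  if (!length(vals)) stop("empty mask", call. = FALSE)
  if (any(vals < 0))
    stop("negative in-mask values; SUV images are non-negative",
         call. = FALSE)
  lev <- array(NA_integer_, dim(image@data))
  lev[mask@data] <- as.integer(floor(vals / w)) + 1L
  new("DiscretizedVolume", levels = lev, binWidth = w,
      nLevels = max(lev[mask@data]), mask = mask)
}
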