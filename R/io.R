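# NIfTI I/O with JSON sidecars for grid/unit metadata.

#' Write an UptakeVolume (or VoiMask) as NIfTI + JSON sidecar
#'
#' The voxel array and spacing go into the NIfTI file; origin, unit and
#' modality (or mask role) into a JSON sidecar next to it.
#'
#' @param x \linkS4class{UptakeVolume} or \linkS4class{VoiMask}.
#' @param path Output path ending in \code{.nii} or \code{.nii.gz}.
#' @return Invisibly, the paths written (nifti, sidecar).
#' @export
writeUptakeVolume <- function(x, path) {
  dat <- if (is(x, "VoiMask")) array(as.numeric(x@data), dim(x@data))
         else x@data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- voxelSpacing(x)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list(origin = voxelOrigin(x), spacing = voxelSpacing(x))
  if (is(x, "VoiMask")) meta$role <- x@role
  else {
    meta$unit <- x@unit
    meta$modality <- x@modality
  }
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Read an UptakeVolume written by \code{\link{writeUptakeVolume}}
#'
#' @param path NIfTI path; the JSON sidecar is read when present.
#' @return An \linkS4class{UptakeVolume} (or \linkS4class{VoiMask} when
#'   the sidecar records a mask role).
#' @export
readUptakeVolume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  dat <- array(as.numeric(img), dim(img))
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else list()
  origin <- if (!is.null(meta$origin)) as.numeric(meta$origin) else c(0, 0, 0)
  if (!is.null(meta$role))
    return(voiMask(dat >= 0.5, spacing, origin, role = meta$role))
  uptakeVolume(dat, spacing, origin,
               unit = if (!is.null(meta$unit)) meta$unit else "Bq/mL",
               modality = if (!is.null(meta$modality)) meta$modality
                          else "none")
}
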