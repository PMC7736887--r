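# Orchestration of the 20-feature radiomic vector.

#' Names of the 20 radiomic features
#' @return Character vector of the feature column names.
#' @export
featureNames <- function() {
  c("mesh_volume", "surface_area", "sphericity", "max_3d_diameter",
    "entropy", "uniformity", "skewness", "kurtosis",
    "standard_deviation",
    "glcm_contrast", "glcm_correlation", "glcm_inverse_difference",
    "glcm_normalized_inverse_difference", "glcm_joint_energy",
    "glcm_joint_entropy",
    "ngtdm_busyness", "ngtdm_coarseness", "ngtdm_complexity",
    "ngtdm_contrast", "ngtdm_strength")
}

#' Extract the 20-feature radiomic vector for one lesion
#'
#' Pipeline: isotropic resampling (default 2 mm, trilinear) ->
#' fixed-bin-width discretization (default w = 0.5) -> morphology
#' (mesh volume cm^3, surface area cm^2, sphericity, maximum 3D
#' diameter cm), first-order intensity (entropy, uniformity, skewness,
#' kurtosis, standard deviation), GLCM and NGTDM texture features.
#'
#' @param image \linkS4class{UptakeVolume} (SUV or SUL).
#' @param mask Tumor \linkS4class{VoiMask}.
#' @param config List overriding \code{target_spacing} (mm, default 2),
#'   \code{bin_width} (default 0.5), \code{smooth_sigma} (mesh
#'   anti-aliasing sigma in voxels, default 0.8).
#' @return One-row data.frame with the 20 \code{\link{featureNames}}
#'   columns; attribute \code{provenance} records the spacing, bin
#'   width and N_g used.
#' @export
extractFeatures <- function(image, mask, config = list()) {
  cfg <- utils::modifyList(
    list(target_spacing = 2, bin_width = 0.5, smooth_sigma = 0.8), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  rs <- stage("resample",
              resampleIsotropic(image, mask, target = cfg$target_spacing))
  disc <- stage("discretize",
                discretizeFBW(rs$image, rs$mask, w = cfg$bin_width))
  morph <- stage("morphology",
                 morphologyFeatures(rs$mask,
                                    smooth_sigma = cfg$smooth_sigma))
  inten <- stage("intensity", intensityFeatures(rs$image, rs$mask, disc))
  glcm <- stage("glcm", glcmFeatures(disc))
  ngtdm <- stage("ngtdm", ngtdmFeatures(disc))
  out <- data.frame(
    mesh_volume = morph$mesh_volume,
    surface_area = morph$surface_area,
    sphericity = morph$sphericity,
    max_3d_diameter = morph$max_3d_diameter,
    entropy = inten$entropy,
    uniformity = inten$uniformity,
    skewness = inten$skewness,
    kurtosis = inten$kurtosis,
    standard_deviation = inten$standard_deviation,
    glcm_contrast = glcm$contrast,
    glcm_correlation = glcm$correlation,
    glcm_inverse_difference = glcm$inverse_difference,
    glcm_normalized_inverse_difference =
      glcm$normalized_inverse_difference,
    glcm_joint_energy = glcm$joint_energy,
    glcm_joint_entropy = glcm$joint_entropy,
    ngtdm_busyness = ngtdm$busyness,
    ngtdm_coarseness = ngtdm$coarseness,
    ngtdm_complexity = ngtdm$complexity,
    ngtdm_contrast = ngtdm$contrast,
    ngtdm_strength = ngtdm$strength)
  attr(out, "provenance") <- list(
    target_spacing = cfg$target_spacing, bin_width = cfg$bin_width,
    n_levels = disc@nLevels, smooth_sigma = cfg$smooth_sigma)
  out
}
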