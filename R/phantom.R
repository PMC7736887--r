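# Digital activity phantom: two breasts, one lesion, a liver region.

#' Phantom geometry defaults
#'
#' Fixed anatomy of the digital phantom, in mm: two parenchyma spheres
#' (ipsilateral breast holding the lesion, contralateral breast for the
#' background VOI), a liver sphere present only in the whole-body field
#' of view, and the axial extent of the breast-only field of view.
#'
#' @return Named list of geometry constants (mm).
#' @export
phantomGeometry <- function() {
  list(
    extent = c(160, 80, 168),        # grid extent, mm
    breast_ipsi_center = c(40, 40, 42),
    breast_contra_center = c(120, 40, 42),
    breast_radius = 35,
    liver_center = c(80, 40, 126),
    liver_radius = 26,
    breast_fov_zmax = 84,            # db FOV: voxel centers with z < this
    crosstalk_center = c(40, 40, 80),
    crosstalk_radius = 10)
}

#' Default phantom generation parameters
#'
#' Uptake ranges in SUV units; one value per phantom is drawn uniformly
#' from each range, emulating inter-patient variation in parenchymal and
#' liver background signal.
#'
#' @return Named list of defaults.
#' @export
phantomParams <- function() {
  list(
    fine_spacing = 0.5,              # mm, fine ground-truth grid
    parenchyma_suv_range = c(0.3, 1.5),
    liver_suv_range = c(1.8, 2.6),
    lesion_suv_range = c(4, 15),
    crosstalk = FALSE,
    crosstalk_suv = 2.5)
}

default_attrs <- function(modality = c("db", "wb"), bodyWeight = 66.6,
                          height = 1.62, uptakeTime = 60) {
  modality <- match.arg(modality)
  patientAttributes(
    sex = "F", bodyWeight = bodyWeight, height = height,
    injectedDose = if (modality == "db") 185.7 else 301.6,
    uptakeTime = uptakeTime)
}

# linear voxel indices inside a sphere, computed slice-by-slice
sphere_indices <- function(dims, spacing, center, radius) {
  xs <- ((seq_len(dims[1]) - 1) * spacing - center[1])^2
  ys <- ((seq_len(dims[2]) - 1) * spacing - center[2])^2
  zs <- ((seq_len(dims[3]) - 1) * spacing - center[3])^2
  xy2 <- outer(xs, ys, "+")
  n12 <- dims[1] * dims[2]
  idx <- lapply(which(zs <= radius^2), function(k)
    which(xy2 <= radius^2 - zs[k]) + (k - 1L) * n12)
  unlist(idx)
}

# Correlated unit-amplitude random field on a sub-grid: Gaussian-smoothed
# white noise, standardized, clipped to [-1, 1].
correlated_field <- function(dims, spacing, length_mm) {
  noise <- array(rnorm(prod(dims)), dims)
  sm <- gaussian_blur3d(noise, fwhm = length_mm, spacing = rep(spacing, 3))
  s <- sd(sm)
  if (s == 0) return(array(0, dims))
  pmin(pmax(sm / (2 * s), -1), 1)
}

#' Build a ground-truth activity phantom
#'
#' Places one spherical lesion with optionally heterogeneous uptake
#' inside the ipsilateral breast of a fixed two-breast + liver geometry,
#' draws per-phantom parenchyma and liver uptake from the configured
#' ranges, and returns the fine-grid ground truth in SUV units.
#'
#' @param lesion A \linkS4class{LesionSpec}.
#' @param seed Integer seed; the phantom is bit-reproducible for a fixed
#'   seed and spec.
#' @param attrs Optional list with elements \code{db} and \code{wb} of
#'   \linkS4class{PatientAttributes}; defaults emulate the study cohort
#'   (66.6 kg, 1.62 m, 185.7 / 301.6 MBq).
#' @param params Named list overriding \code{\link{phantomParams}} entries.
#' @return An \linkS4class{ActivityPhantom}.
#' @examples
#' ph <- buildPhantom(lesionSpec(diameter = 2, heterogeneityAmplitude = 0),
#'                    seed = 1)
#' ph
#' @export
buildPhantom <- function(lesion, seed, attrs = NULL, params = list()) {
  stopifnot(is(lesion, "LesionSpec"))
  validObject(lesion)
  p <- utils::modifyList(phantomParams(), params)
  geo <- phantomGeometry()
  r_les <- lesion@diameter * 10 / 2   # cm -> mm radius
  off_center <- sqrt(sum((lesion@center - geo$breast_ipsi_center)^2))
  if (off_center + r_les > geo$breast_radius)
    stop(sprintf(
      "lesion (d = %.2f cm at [%s] mm) extends outside the breast volume",
      lesion@diameter, paste(lesion@center, collapse = ", ")),
      call. = FALSE)
  sp <- p$fine_spacing
  if (sp > 0.5) stop("fine_spacing must be <= 0.5 mm", call. = FALSE)
  dims <- as.integer(round(geo$extent / sp))

  if (is.null(attrs))
    attrs <- list(db = default_attrs("db"), wb = default_attrs("wb"))

  with_seed(seed, {
    suv_par <- runif(1, p$parenchyma_suv_range[1], p$parenchyma_suv_range[2])
    suv_liv <- runif(1, p$liver_suv_range[1], p$liver_suv_range[2])

    labels <- array(0L, dims)
    labels[sphere_indices(dims, sp, geo$breast_ipsi_center,
                          geo$breast_radius)] <- 1L
    labels[sphere_indices(dims, sp, geo$breast_contra_center,
                          geo$breast_radius)] <- 1L
    labels[sphere_indices(dims, sp, geo$liver_center,
                          geo$liver_radius)] <- 3L
    if (isTRUE(p$crosstalk)) {
      ct <- sphere_indices(dims, sp, geo$crosstalk_center,
                           geo$crosstalk_radius)
      ct <- ct[labels[ct] == 0L]
      labels[ct] <- 4L
    }
    les_idx <- sphere_indices(dims, sp, lesion@center, r_les)
    labels[les_idx] <- 2L
    in_les <- array(FALSE, dims)
    in_les[les_idx] <- TRUE

    activity <- array(0, dims)
    activity[labels == 1L] <- suv_par
    activity[labels == 3L] <- suv_liv
    if (isTRUE(p$crosstalk)) activity[labels == 4L] <- p$crosstalk_suv

    if (lesion@heterogeneityAmplitude > 0) {
      bb <- mask_bbox(in_les, margin = 2L)
      sub_dims <- bb$hi - bb$lo + 1L
      fld <- correlated_field(sub_dims, sp, lesion@heterogeneityLength)
      sub <- array(0, sub_dims)
      les_sub <- in_les[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                        bb$lo[3]:bb$hi[3]]
      sub[les_sub] <- lesion@baseUptake *
        (1 + lesion@heterogeneityAmplitude * fld[les_sub])
      act_sub <- activity[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                          bb$lo[3]:bb$hi[3]]
      act_sub[les_sub] <- sub[les_sub]
      activity[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
               bb$lo[3]:bb$hi[3]] <- act_sub
    } else {
      activity[in_les] <- lesion@baseUptake
    }

    new("ActivityPhantom", activity = activity, labels = labels,
        spacing = rep(sp, 3), origin = c(0, 0, 0), lesion = lesion,
        attrs = attrs, seed = as.integer(seed),
        params = c(p, list(parenchyma_suv = suv_par, liver_suv = suv_liv,
                           geometry = geo)))
  })
}

#' True lesion volume of a phantom (mL), by voxel count
#'
#' @param phantom An \linkS4class{ActivityPhantom}.
#' @return Lesion volume in mL (count of lesion-labeled voxels times the
#'   fine voxel volume).
#' @export
trueLesionVolume <- function(phantom) {
  sum(phantom@labels == 2L) * prod(phantom@spacing) / 1000
}

#' Generate a paired simulated cohort
#'
#' Each case is one phantom imaged under both the db and wb acquisition
#' configurations; per-case seeds are derived deterministically from the
#' master seed. Lesion diameters are drawn from a two-component mixture
#' emulating the study cohort (40% small lesions near the 2.5 cm cutoff,
#' 60% larger lesions), by default spanning 2.1-5.6 cm.
#'
#' @param n Number of cases (>= 1).
#' @param seed Master seed.
#' @param db_config,wb_config \linkS4class{AcquisitionConfig}s; defaults
#'   \code{acquisitionConfig("db")} / \code{acquisitionConfig("wb")}.
#' @param diameter_range Length-2 cm range; when supplied, diameters are
#'   drawn uniformly from it instead of the cohort mixture.
#' @param params Phantom parameter overrides, see \code{\link{phantomParams}}.
#' @param keep_phantom Keep each full phantom in the result (memory-heavy;
#'   default FALSE retains only ground-truth scalars).
#' @return List of cases; each has elements \code{id}, \code{db}, \code{wb}
#'   (\linkS4class{UptakeVolume}s), \code{attrs}, \code{lesion},
#'   \code{truth} (list: d_MRI_cm, true_volume_mL, lesion_center,
#'   liver_center, contra_center, parenchyma_suv, liver_suv, seed).
#' @export
generateCohort <- function(n, seed, db_config = acquisitionConfig("db"),
                           wb_config = acquisitionConfig("wb"),
                           diameter_range = NULL, params = list(),
                           keep_phantom = FALSE) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(diameter_range) &&
      (length(diameter_range) != 2 || diff(diameter_range) < 0 ||
       diameter_range[1] <= 0))
    stop("diameter_range must be an increasing positive length-2 range",
         call. = FALSE)
  p <- utils::modifyList(phantomParams(), params)
  geo <- phantomGeometry()
  case_seeds <- with_seed(seed, sample.int(2147483646L, n))
  lapply(seq_len(n), function(i) {
    cs <- case_seeds[i]
    draws <- with_seed(cs, {
      d <- if (!is.null(diameter_range)) {
        runif(1, diameter_range[1], diameter_range[2])
      } else if (runif(1) < 0.4) runif(1, 2.1, 2.5) else runif(1, 3.0, 5.6)
      list(
        d = d,
        base = runif(1, p$lesion_suv_range[1], p$lesion_suv_range[2]),
        weight = runif(1, 61, 72),
        height = runif(1, 1.50, 1.75),
        dose_db = runif(1, 160, 210),
        dose_wb = runif(1, 270, 335))
    })
    attrs <- list(
      db = patientAttributes(sex = "F", bodyWeight = draws$weight,
                             height = draws$height,
                             injectedDose = draws$dose_db),
      wb = patientAttributes(sex = "F", bodyWeight = draws$weight,
                             height = draws$height,
                             injectedDose = draws$dose_wb))
    les <- lesionSpec(diameter = draws$d, baseUptake = draws$base)
    ph <- buildPhantom(les, seed = cs %% 1000000L + 1L, attrs = attrs,
                       params = params)
    db <- simulateAcquisition(ph, db_config, seed = cs %% 1000000L + 2L)
    wb <- simulateAcquisition(ph, wb_config, seed = cs %% 1000000L + 3L)
    out <- list(
      id = sprintf("case%02d", i), db = db, wb = wb, attrs = attrs,
      lesion = les,
      truth = list(
        d_MRI_cm = draws$d, true_volume_mL = trueLesionVolume(ph),
        lesion_center = les@center, liver_center = geo$liver_center,
        contra_center = geo$breast_contra_center,
        parenchyma_suv = ph@params$parenchyma_suv,
        liver_suv = ph@params$liver_suv, seed = cs))
    if (keep_phantom) out$phantom <- ph
    out
  })
}
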