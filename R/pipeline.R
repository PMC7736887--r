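# End-to-end orchestration: simulate -> quantify -> featurize -> compare.

#' Pipeline run configuration
#'
#' Defaults equal the study parameters: segmentation thresholds
#' SUV >= 3.0 (db) / 2.5 (wb), 2 mm isotropic resampling, bin width
#' 0.5, 1.2 cm peak kernel, 40% MTV fraction, 2.5 cm d_MRI cutoff.
#'
#' @param n Cohort size (default 10).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param db_config,wb_config \linkS4class{AcquisitionConfig}s.
#' @param db_threshold,wb_threshold Segmentation SUV thresholds.
#' @param target_spacing,bin_width,peak_kernel_cm,mtv_fraction,cutoff_cm
#'   Analysis parameters (see module functions).
#' @param diameter_range Optional uniform lesion-diameter range (cm).
#' @param write_volumes Write per-case NIfTI volumes (default TRUE).
#' @param phantom_params Overrides for \code{\link{phantomParams}}.
#' @return Named list (class \code{dualPETConfig}).
#' @export
runConfig <- function(n = 10, seed = 1, out_dir = tempfile("dualPET_run_"),
                      db_config = acquisitionConfig("db"),
                      wb_config = acquisitionConfig("wb"),
                      db_threshold = 3.0, wb_threshold = 2.5,
                      target_spacing = 2, bin_width = 0.5,
                      peak_kernel_cm = 1.2, mtv_fraction = 0.40,
                      cutoff_cm = 2.5, diameter_range = NULL,
                      write_volumes = TRUE, phantom_params = list()) {
  cfg <- list(
    n = n, seed = seed, out_dir = out_dir, db_config = db_config,
    wb_config = wb_config, db_threshold = db_threshold,
    wb_threshold = wb_threshold, target_spacing = target_spacing,
    bin_width = bin_width, peak_kernel_cm = peak_kernel_cm,
    mtv_fraction = mtv_fraction, cutoff_cm = cutoff_cm,
    diameter_range = diameter_range, write_volumes = write_volumes,
    phantom_params = phantom_params)
  num <- c("n", "seed", "db_threshold", "wb_threshold", "target_spacing",
           "bin_width", "peak_kernel_cm", "mtv_fraction", "cutoff_cm")
  bad <- num[vapply(cfg[num], function(v) !is.numeric(v) || v <= 0,
                    logical(1))]
  if (length(bad))
    stop("non-positive config parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(cfg) <- "dualPETConfig"
  cfg
}

# serializable echo of a config (for the YAML provenance file)
config_as_list <- function(cfg) {
  enc <- function(ac) list(modality = ac@modality, spacing = ac@spacing,
                           fwhm = ac@fwhm, noiseCoef = ac@noiseCoef,
                           fov = ac@fov)
  out <- unclass(cfg)
  out$db_config <- enc(cfg$db_config)
  out$wb_config <- enc(cfg$wb_config)
  out
}

#' Re-parse an echoed provenance config
#' @param path YAML file written by \code{\link{runPipeline}}.
#' @return A \code{dualPETConfig} equal to the one that produced it.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  dec <- function(l) acquisitionConfig(l$modality, spacing = l$spacing,
                                       fwhm = l$fwhm,
                                       noiseCoef = l$noiseCoef, fov = l$fov)
  runConfig(
    n = y$n, seed = y$seed, out_dir = y$out_dir,
    db_config = dec(y$db_config), wb_config = dec(y$wb_config),
    db_threshold = y$db_threshold, wb_threshold = y$wb_threshold,
    target_spacing = y$target_spacing, bin_width = y$bin_width,
    peak_kernel_cm = y$peak_kernel_cm, mtv_fraction = y$mtv_fraction,
    cutoff_cm = y$cutoff_cm,
    diameter_range = if (length(y$diameter_range))
      as.numeric(y$diameter_range) else NULL,
    write_volumes = y$write_volumes,
    phantom_params = if (length(y$phantom_params)) y$phantom_params
                     else list())
}

# seed voxel for segmentation: supra-oriented local max near the known
# lesion center (replaces the operator's click)
lesion_seed_index <- function(suv, center_mm, radius_mm = 6) {
  d <- dim(suv@data)
  ctr <- pmin(pmax(round((center_mm - suv@origin) / suv@spacing) + 1, 1), d)
  off <- sphere_offsets(radius_mm, suv@spacing)
  pts <- sweep(off, 2, as.integer(ctr), "+")
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 &
    pts[, 2] <= d[2] & pts[, 3] >= 1 & pts[, 3] <= d[3]
  pts <- pts[ok, , drop = FALSE]
  vals <- suv@data[pts[, 1] + d[1] * (pts[, 2] - 1) +
                     d[1] * d[2] * (pts[, 3] - 1)]
  as.integer(pts[which.max(vals), ])
}

# quantify one simulated case on one modality
quantify_case <- function(case, modality, cfg) {
  vol <- case[[modality]]
  at <- case$attrs[[modality]]
  suv <- computeSUV(vol, at, decayParams(interval = at@uptakeTime))
  sul <- suvToSUL(suv, at)
  seed_idx <- lesion_seed_index(suv, case$truth$lesion_center)
  thr <- if (modality == "db") cfg$db_threshold else cfg$wb_threshold
  tumor <- segmentTumor(suv, modality, seed_idx, threshold = thr)
  d <- dim(suv@data)
  to_idx <- function(mm) pmin(pmax(round((mm - suv@origin) / suv@spacing)
                                   + 1, 1), d)
  bgs <- list()
  bgs$contralateral <- backgroundVoi(
    sul, "contralateral", center = to_idx(case$truth$contra_center),
    shape = if (modality == "db") "cylinder" else "sphere")
  if (modality == "wb")
    bgs$liver <- backgroundVoi(sul, "liver",
                               center = to_idx(case$truth$liver_center))
  met <- uptakeMetrics(sul, suv, tumor, bgs, d_MRI = case$truth$d_MRI_cm,
                       fraction = cfg$mtv_fraction)
  feats <- extractFeatures(suv, tumor,
                           config = list(target_spacing = cfg$target_spacing,
                                         bin_width = cfg$bin_width))
  list(suv = suv, sul = sul, tumor = tumor, metrics = met,
       features = feats)
}

#' Run the full simulate -> quantify -> featurize -> compare pipeline
#'
#' Generates a paired cohort, computes uptake metrics and the 20
#' radiomic features per case and modality, compares modalities
#' (Hodges-Lehmann differences, Wilcoxon signed-rank) and writes the
#' stratified summary, all under \code{cfg$out_dir}. Every file written
#' is recorded in the returned manifest.
#'
#' @param cfg A \code{\link{runConfig}}.
#' @return Invisibly, a list: \code{manifest} (data.frame: file, stage),
#'   \code{metrics}, \code{features}, \code{comparison_metrics},
#'   \code{comparison_features}, \code{stratified}.
#' @export
runPipeline <- function(cfg = runConfig()) {
  stopifnot(inherits(cfg, "dualPETConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  reg <- function(f) files <<- c(files, f)
  logline <- function(...) message("[dualPET] ", sprintf(...))

  logline("simulating %d paired cases (seed %d)", cfg$n, cfg$seed)
  cohort <- generateCohort(cfg$n, cfg$seed, cfg$db_config, cfg$wb_config,
                           diameter_range = cfg$diameter_range,
                           params = cfg$phantom_params)

  metrics <- list(); feats <- list(); hists <- list()
  for (case in cohort) {
    for (mod in c("db", "wb")) {
      res <- tryCatch(
        quantify_case(case, mod, cfg),
        error = function(e) stop(sprintf("case %s, modality %s: %s",
                                         case$id, mod,
                                         conditionMessage(e)),
                                 call. = FALSE))
      metrics[[paste(case$id, mod)]] <-
        cbind(data.frame(case = case$id, modality = mod), res$metrics)
      feats[[paste(case$id, mod)]] <-
        cbind(data.frame(case = case$id, modality = mod), res$features)
      h <- intensityHistogram(res$suv, res$tumor)
      hists[[paste(case$id, mod)]] <- data.frame(
        case = case$id, modality = mod, bin_lo = head(h$breaks, -1),
        bin_hi = h$breaks[-1], count = h$counts)
      if (cfg$write_volumes) {
        base <- file.path(cfg$out_dir, sprintf("%s_%s", case$id, mod))
        reg(writeUptakeVolume(res$suv, paste0(base, "_suv.nii")))
        reg(writeUptakeVolume(res$tumor, paste0(base, "_tumor.nii")))
      }
    }
    side <- file.path(cfg$out_dir, sprintf("%s_truth.json", case$id))
    jsonlite::write_json(case$truth, side, auto_unbox = TRUE, digits = NA)
    reg(side)
    logline("case %s quantified (d = %.2f cm)", case$id,
            case$truth$d_MRI_cm)
  }
  metrics <- do.call(rbind, metrics); rownames(metrics) <- NULL
  feats <- do.call(rbind, feats); rownames(feats) <- NULL
  hists <- do.call(rbind, hists); rownames(hists) <- NULL

  wide <- function(df, cols) {
    db <- df[df$modality == "db", c("case", cols)]
    wb <- df[df$modality == "wb", c("case", cols)]
    list(db = db, wb = wb)
  }
  met_cols <- c("SUL_max", "SUL_mean", "SUL_peak", "MTV_mL", "TLG",
                "TBR_liver", "TBR_contralateral")
  cmp_met <- {
    w <- wide(metrics, setdiff(met_cols, "TBR_liver"))
    compareModalities(w$db, w$wb)
  }
  cmp_feat <- {
    w <- wide(feats, featureNames())
    compareModalities(w$db, w$wb)
  }
  strat <- stratifiedSummary(metrics, cutoff = cfg$cutoff_cm,
                             metrics_cols = met_cols)

  wr <- function(obj, name, stage) {
    f <- file.path(cfg$out_dir, name)
    write.csv(obj, f, row.names = FALSE)
    reg(f)
    f
  }
  wr(metrics, "uptake_metrics.csv")
  wr(feats, "radiomic_features.csv")
  wr(hists, "intensity_histograms.csv")
  wr(cmp_met, "comparison_metrics.csv")
  wr(cmp_feat, "comparison_features.csv")
  wr(strat$summary, "stratified_summary.csv")
  fc_path <- file.path(cfg$out_dir, "fold_changes.json")
  jsonlite::write_json(strat$fold_change, fc_path, digits = NA)
  reg(fc_path)
  cohort_manifest <- data.frame(
    case = vapply(cohort, `[[`, character(1), "id"),
    d_MRI_cm = vapply(cohort, function(x) x$truth$d_MRI_cm, numeric(1)),
    true_volume_mL = vapply(cohort, function(x) x$truth$true_volume_mL,
                            numeric(1)),
    seed = vapply(cohort, function(x) x$truth$seed, numeric(1)))
  wr(cohort_manifest, "cohort.csv")
  cfg_path <- file.path(cfg$out_dir, "run_config.yaml")
  yaml::write_yaml(config_as_list(cfg), cfg_path)
  reg(cfg_path)

  manifest <- data.frame(file = files)
  man_path <- file.path(cfg$out_dir, "manifest.txt")
  writeLines(files, man_path)
  logline("wrote %d files to %s", length(files) + 1L, cfg$out_dir)
  invisible(list(manifest = manifest, metrics = metrics,
                 features = feats, comparison_metrics = cmp_met,
                 comparison_features = cmp_feat, stratified = strat,
                 cohort = cohort_manifest, out_dir = cfg$out_dir))
}

#' In-mask intensity histogram
#'
#' Equal-width bins spanning the in-mask value range (default 50 bins);
#' a constant ROI gets a degenerate range widened by machine epsilon so
#' every voxel lands in one occupied bin.
#'
#' @param image \linkS4class{UptakeVolume}.
#' @param mask \linkS4class{VoiMask}, non-empty.
#' @param n_bins Number of bins (default 50).
#' @return List: breaks (length n_bins + 1), counts, mids.
#' @export
intensityHistogram <- function(image, mask, n_bins = 50) {
  stopifnot(is(image, "UptakeVolume"), is(mask, "VoiMask"))
  stop_if_not_congruent(image, mask, "image and mask")
  vals <- image@data[mask@data]
  if (!length(vals)) stop("empty mask", call. = FALSE)
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) hi <- lo + max(abs(lo), 1) * .Machine$double.eps * n_bins
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(vals, breaks), n_bins),
                     nbins = n_bins)
  list(breaks = breaks, counts = counts,
       mids = (head(breaks, -1) + breaks[-1]) / 2)
}
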