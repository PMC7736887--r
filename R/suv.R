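# SUV / SUL conversion.

#' Decay parameters for SUV computation
#'
#' @param halfLife Radionuclide half-life in min (F-18: 109.77).
#' @param interval Minutes between dose calibration and the scan; the
#'   injected dose is decayed over this interval before normalization.
#' @return A named list used by \code{\link{computeSUV}}.
#' @export
decayParams <- function(halfLife = 109.77, interval = 0) {
  if (halfLife <= 0) stop("halfLife must be > 0", call. = FALSE)
  if (interval < 0) stop("interval must be >= 0", call. = FALSE)
  list(halfLife = halfLife, interval = interval)
}

#' Convert activity concentration to SUV
#'
#' SUV = C / (decay-corrected dose / body weight), with the dose in Bq
#' and weight in g, so that SUV is the usual g/mL quantity (reported as
#' mL^-1 under unit tissue density). The dose at scan time is the
#' injected dose decayed over \code{decay$interval}.
#'
#' @param image \linkS4class{UptakeVolume} in Bq/mL.
#' @param attrs \linkS4class{PatientAttributes} (dose in MBq, weight kg).
#' @param decay \code{\link{decayParams}}; default: no decay interval.
#' @return \linkS4class{UptakeVolume} tagged SUV.
#' @examples
#' at <- patientAttributes(bodyWeight = 66.6, height = 1.62,
#'                         injectedDose = 185)
#' v <- uptakeVolume(array(10000, c(2, 2, 2)), 4, unit = "Bq/mL")
#' max(voxelData(computeSUV(v, at)))  # 3.6
#' @export
computeSUV <- function(image, attrs, decay = decayParams()) {
  stopifnot(is(image, "UptakeVolume"), is(attrs, "PatientAttributes"))
  if (image@unit != "Bq/mL")
    stop("computeSUV expects an image in Bq/mL", call. = FALSE)
  if (attrs@injectedDose <= 0 || attrs@bodyWeight <= 0)
    stop("dose and body weight must be positive", call. = FALSE)
  dose_bq <- attrs@injectedDose * 1e6 *
    2^(-decay$interval / decay$halfLife)
  suv <- image@data / (dose_bq / (attrs@bodyWeight * 1000))
  uptakeVolume(suv, image@spacing, image@origin, unit = "SUV",
               modality = image@modality)
}

#' Lean body mass (kg)
#'
#' Janmahasatian (default): female LBM = 9270 W / (8780 + 244 BMI),
#' male LBM = 9270 W / (6680 + 216 BMI), BMI = W / H^2 (W kg, H m).
#' James: female LBM = 1.07 W - 148 (W / H_cm)^2, male
#' 1.10 W - 128 (W / H_cm)^2. "identity" returns W (turns SUL into SUV).
#'
#' @param attrs \linkS4class{PatientAttributes}.
#' @param formula "janmahasatian", "james" or "identity".
#' @return Lean body mass in kg.
#' @export
leanBodyMass <- function(attrs,
                         formula = c("janmahasatian", "james", "identity")) {
  formula <- match.arg(formula)
  W <- attrs@bodyWeight
  if (formula == "identity") return(W)
  if (is.na(attrs@height) || attrs@height <= 0)
    stop("height is required for the ", formula, " formula", call. = FALSE)
  if (formula == "janmahasatian") {
    bmi <- W / attrs@height^2
    if (attrs@sex == "F") 9270 * W / (8780 + 244 * bmi)
    else 9270 * W / (6680 + 216 * bmi)
  } else {
    hcm <- attrs@height * 100
    if (attrs@sex == "F") 1.07 * W - 148 * (W / hcm)^2
    else 1.10 * W - 128 * (W / hcm)^2
  }
}

#' Convert SUV to SUL (lean-body-mass normalization)
#'
#' SUL = SUV * LBM / W, the PERCIST normalization.
#'
#' @param image \linkS4class{UptakeVolume} in SUV.
#' @param attrs \linkS4class{PatientAttributes}.
#' @param formula LBM formula, see \code{\link{leanBodyMass}}.
#' @return \linkS4class{UptakeVolume} tagged SUL.
#' @export
suvToSUL <- function(image, attrs,
                     formula = c("janmahasatian", "james", "identity")) {
  stopifnot(is(image, "UptakeVolume"))
  if (image@unit != "SUV")
    stop("suvToSUL expects an image in SUV units", call. = FALSE)
  lbm <- leanBodyMass(attrs, formula)
  uptakeVolume(image@data * (lbm / attrs@bodyWeight), image@spacing,
               image@origin, unit = "SUL", modality = image@modality)
}
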