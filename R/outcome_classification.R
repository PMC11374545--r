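#' Albuminuria thresholds
#'
#' Sex-specific urinary albumin-to-creatinine ratio cut-offs (mg/mmol) above
#' which albuminuria is present. Defaults follow Australian survey
#' conventions (2.5 for males, 3.5 for females) and are configurable because
#' the exact cut-off used by the national survey's CKD flag is not published.
#'
#' @param male,female thresholds in mg/mmol.
#' @return named numeric vector.
#' @export
acr_thresholds <- function(male = 2.5, female = 3.5) {
  c(male = male, female = female)
}

#' Classify chronic kidney disease from eGFR and ACR
#'
#' Staging rules: eGFR < 60 ml/min/1.73m2 is CKD stages 3-5 (moderate-severe)
#' regardless of ACR; eGFR >= 60 with albuminuria (ACR at or above the
#' sex-specific threshold) is stages 1-2; eGFR >= 60 without albuminuria is
#' no CKD. eGFR exactly 60 falls on the ">= 60" side (the stage 3-5 rule is
#' strictly "less than 60").
#'
#' @param egfr estimated glomerular filtration rate, ml/min/1.73m2.
#' @param acr urinary albumin-to-creatinine ratio, mg/mmol.
#' @param sex character vector, "male"/"female".
#' @param thresholds from [acr_thresholds()].
#' @return data.frame with status (factor none/stage1_2/stage3_5), any_ckd,
#'   moderate_severe.
#' @export
classify_ckd <- function(egfr, acr, sex, thresholds = acr_thresholds()) {
  if (any(is.na(egfr)) || any(is.na(acr)))
    stop("missing eGFR or ACR: participant cannot be classified")
  stopifnot(all(egfr > 0), all(acr >= 0), all(sex %in% c("male", "female")))
  albuminuria <- acr >= thresholds[sex]
  status <- ifelse(egfr < 60, "stage3_5",
                   ifelse(albuminuria, "stage1_2", "none"))
  status <- factor(status, levels = c("none", "stage1_2", "stage3_5"))
  data.frame(status = status, any_ckd = status != "none",
             moderate_severe = status == "stage3_5")
}

#' Select the analysis blood-pressure reading
#'
#' The survey protocol takes a third measurement when the first two systolic
#' or diastolic readings differ by more than 10 mmHg. For analysis, with two
#' readings the second is used; with three, the mean of the second and third.
#' The first reading is never used.
#'
#' @param readings numeric matrix with columns sys1, dia1, sys2, dia2 and
#'   optionally sys3, dia3 (NA where no third reading was taken), one row per
#'   participant; or a numeric vector of length 4 or 6 for one participant.
#' @return data.frame with columns systolic, diastolic (mmHg).
#' @export
select_bp <- function(readings) {
  if (is.null(dim(readings))) readings <- matrix(readings, nrow = 1L)
  if (ncol(readings) < 4L)
    stop("blood-pressure protocol requires at least two readings")
  if (any(is.na(readings[, 1:4])))
    stop("first two blood-pressure readings are incomplete")
  sys <- readings[, 3L]
  dia <- readings[, 4L]
  if (ncol(readings) >= 6L) {
    third <- !is.na(readings[, 5L]) & !is.na(readings[, 6L])
    sys[third] <- (readings[third, 3L] + readings[third, 5L]) / 2
    dia[third] <- (readings[third, 4L] + readings[third, 6L]) / 2
  }
  data.frame(systolic = sys, diastolic = dia)
}

#' Hypertension flag
#'
#' Blood pressure greater than or equal to 140/90 mmHg, i.e. systolic >= 140
#' or diastolic >= 90, on the analysis reading from [select_bp()].
#'
#' @param systolic,diastolic mmHg.
#' @return logical vector.
#' @export
classify_hypertension <- function(systolic, diastolic) {
  systolic >= 140 | diastolic >= 90
}

#' Diabetes-risk category from HbA1c
#'
#' HbA1c < 6\% is normal, 6-6.4\% at risk of diabetes, >= 6.5\% diabetes.
#'
#' @param hba1c glycated haemoglobin, percent.
#' @return factor with levels normal, at_risk, diabetes.
#' @export
classify_diabetes_risk <- function(hba1c) {
  stopifnot(all(hba1c > 0))
  cut(hba1c, breaks = c(0, 6, 6.5, Inf), right = FALSE,
      labels = c("normal", "at_risk", "diabetes"))
}

#' Body mass index (Quetelet, kg/m2)
#'
#' @param height_cm height in cm.
#' @param weight_kg weight in kg.
#' @return numeric, kg/m2.
#' @export
bmi <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive")
  weight_kg / (height_cm / 100)^2
}

#' Classify a cohort's health outcomes
#'
#' Applies all rule-based classifiers to a biomarker table: CKD status,
#' selected blood pressure, hypertension, diabetes risk and BMI.
#'
#' @param biomarkers data.frame with one row per participant and columns
#'   participant_id, egfr, acr, sex, hba1c, height_cm, weight_kg,
#'   sys1, dia1, sys2, dia2, sys3, dia3 (last two NA when only two readings).
#' @param thresholds albuminuria thresholds ([acr_thresholds()]).
#' @return data.frame with participant_id, ckd_status, any_ckd,
#'   moderate_severe, systolic, diastolic, hypertension, diabetes_risk,
#'   diabetes, bmi.
#' @export
classify_outcomes <- function(biomarkers, thresholds = acr_thresholds()) {
  ckd <- classify_ckd(biomarkers$egfr, biomarkers$acr, biomarkers$sex,
                      thresholds)
  bpcols <- intersect(c("sys1", "dia1", "sys2", "dia2", "sys3", "dia3"),
                      names(biomarkers))
  bp <- select_bp(as.matrix(biomarkers[, bpcols]))
  risk <- classify_diabetes_risk(biomarkers$hba1c)
  data.frame(participant_id = biomarkers$participant_id,
             ckd_status = ckd$status, any_ckd = ckd$any_ckd,
             moderate_severe = ckd$moderate_severe,
             systolic = bp$systolic, diastolic = bp$diastolic,
             hypertension = classify_hypertension(bp$systolic, bp$diastolic),
             diabetes_risk = risk, diabetes = risk == "diabetes",
             bmi = bmi(biomarkers$height_cm, biomarkers$weight_kg),
             stringsAsFactors = FALSE)
}
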