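#' Japanese serum-creatinine eGFR equation
#'
#' `eGFR = 194 * Age^-0.287 * Cre^-1.094`, multiplied by 0.739 for
#' females. Units: mL/min/1.73 m^2, age in years, creatinine in mg/dL.
#' Vectorised over all three arguments.
#'
#' @param age age in years, > 0.
#' @param sex `"male"` or `"female"`.
#' @param creatinine serum creatinine, mg/dL, > 0.
#' @return estimated GFR, mL/min/1.73 m^2.
#' @examples
#' egfr_japanese(1, "male", 1.0)    # 194
#' egfr_japanese(50, "male", 1.0)
#' @export
egfr_japanese <- function(age, sex, creatinine) {
  if (any(!is.finite(age)) || any(age <= 0))
    stop_domain("age must be > 0")
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop_domain("creatinine must be > 0")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop_domain("sex must be 'male' or 'female'")
  194 * age^(-0.287) * creatinine^(-1.094) * ifelse(sex == "female", 0.739, 1)
}

#' CKD stage from eGFR and a kidney-damage marker
#'
#' Staging follows the K/DOQI eGFR bands (configurable): stage 1 >= 90,
#' stage 2 60-89, stage 3 30-59, stage 4 15-29, stage 5 < 15. Stages 1 and
#' 2 require evidence of kidney damage (proteinuria, pathological or
#' imaging abnormality); with eGFR >= 60 and no damage marker there is no
#' CKD and the function returns 0.
#'
#' @param egfr estimated GFR, mL/min/1.73 m^2, >= 0. Vectorised.
#' @param kidney_damage logical: kidney-damage marker present.
#' @param bands decreasing numeric vector of the four stage cutoffs
#'   (defaults `c(90, 60, 30, 15)`).
#' @return integer stage 1-5, or 0 for "no CKD".
#' @export
ckd_stage <- function(egfr, kidney_damage, bands = c(90, 60, 30, 15)) {
  if (any(!is.finite(egfr)) || any(egfr < 0))
    stop_domain("egfr must be finite and >= 0")
  if (length(bands) != 4L || is.unsorted(rev(bands)))
    stop_domain("bands must be four decreasing cutoffs")
  kidney_damage <- rep_len(as.logical(kidney_damage), length(egfr))
  stage <- ifelse(egfr >= bands[1], 1L,
           ifelse(egfr >= bands[2], 2L,
           ifelse(egfr >= bands[3], 3L,
           ifelse(egfr >= bands[4], 4L, 5L))))
  ifelse(stage <= 2L & !kidney_damage, 0L, stage)
}

#' Classify birth weight as low or normal
#'
#' Low birth weight (LBW) is a birth weight strictly below 2500 g. Where
#' the exact weight is unknown (common for elderly patients) the interview
#' fallback records a categorical answer, which passes through.
#'
#' @param birth_weight numeric grams, or one of `"low"`, `"normal"`,
#'   `"unknown"` (categorical interview answers). Vectorised; `NA` maps to
#'   `"unknown"`.
#' @return character vector: `"low"`, `"normal"` or `"unknown"`.
#' @examples
#' classify_lbw(c(2499, 2500, NA))
#' classify_lbw("normal")
#' @export
classify_lbw <- function(birth_weight) {
  if (is.numeric(birth_weight)) {
    if (any(birth_weight < 0, na.rm = TRUE))
      stop_domain("birth weight cannot be negative")
    return(ifelse(is.na(birth_weight), "unknown",
                  ifelse(birth_weight < 2500, "low", "normal")))
  }
  bw <- as.character(birth_weight)
  bw[is.na(bw)] <- "unknown"
  if (!all(bw %in% c("low", "normal", "unknown")))
    stop_domain("categorical birth weight must be 'low', 'normal' or 'unknown'")
  bw
}

#' Screen a patient against the enrollment eligibility rules
#'
#' Inclusion: (1) CKD present, (2) undergoing a needle biopsy of the
#' kidney, (3) signed consent, (4) age over 14 years, (5) guardian consent
#' additionally required under age 20. Exclusion: severe laterality in
#' kidney size or function; prior cancer unless free of it for more than
#' one year before the biopsy. All failures are enumerated, not just the
#' first.
#'
#' @param baseline a list or one-row data frame with fields `age`,
#'   `has_ckd`, `biopsy_planned`, `consent`, `guardian_consent` (only
#'   consulted under age 20), `severe_laterality`, `cancer_history`, and
#'   `years_since_cancer` (only consulted when `cancer_history` is TRUE).
#' @return list with `eligible` (logical) and `reasons` (character vector
#'   of every failed rule; empty when eligible).
#' @export
check_eligibility <- function(baseline) {
  b <- as.list(baseline)
  reasons <- character()
  if (!isTRUE(as.logical(b$has_ckd)))
    reasons <- c(reasons, "no CKD diagnosis")
  if (!isTRUE(as.logical(b$biopsy_planned)))
    reasons <- c(reasons, "no needle biopsy of the kidney")
  if (!isTRUE(as.logical(b$consent)))
    reasons <- c(reasons, "consent not signed")
  age <- as.numeric(b$age)
  if (!is.finite(age) || age <= 14)
    reasons <- c(reasons, "age not over 14 years")
  if (is.finite(age) && age > 14 && age < 20 &&
      !isTRUE(as.logical(b$guardian_consent)))
    reasons <- c(reasons, "guardian consent required under age 20")
  if (isTRUE(as.logical(b$severe_laterality)))
    reasons <- c(reasons, "severe laterality in kidney size or function")
  if (isTRUE(as.logical(b$cancer_history))) {
    ys <- as.numeric(b$years_since_cancer %||% NA)
    if (!is.finite(ys) || ys <= 1)
      reasons <- c(reasons, "cancer not in remission for more than 1 year")
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}
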