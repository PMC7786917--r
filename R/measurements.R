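# Graded deficit levels from raw anthropometric/biomarker values.
#
# The instrument codes four items from measurements rather than self-report:
# BMI (item 10), random blood sugar (item 17), GDS-15 depression score
# (item 20) and blood pressure (item 22). The RBS bands are part of the
# instrument itself; the BMI, BP and GDS cut points are package defaults
# (WHO adult BMI bands, WHO/ISH hypertension grades, standard GDS-15
# screening bands) and are configurable.

graded_level <- function(label, weight) {
  out <- data.frame(label = label, weight = weight, stringsAsFactors = FALSE)
  class(out) <- c("fi30_graded", "data.frame")
  out
}

check_measure <- function(x, name, lo = -Inf, hi = Inf, allow_na = TRUE) {
  x <- as.numeric(x)
  bad <- !is.na(x) & (x <= lo | x >= hi)
  if (any(bad)) {
    fi30_stop("fi30_validation_error",
              sprintf("%s value(s) out of plausible range (%g, %g): %s",
                      name, lo, hi, paste(unique(x[bad]), collapse = ", ")))
  }
  if (!allow_na && any(is.na(x))) {
    fi30_stop("fi30_validation_error", sprintf("%s must not be missing", name))
  }
  x
}

#' Body mass index from height and weight
#'
#' BMI = weight (kg) / height (m)^2, unrounded. Inputs outside a
#' plausibility screen (height in (0.5, 2.5) m, weight in (20, 300) kg)
#' raise a validation error.
#'
#' @param height_m height in metres; vectorized.
#' @param weight_kg weight in kilograms; vectorized.
#' @return Numeric vector of BMI values (kg/m^2); `NA` in, `NA` out.
#' @examples
#' compute_bmi(1.6, 64)  # 25
#' @export
compute_bmi <- function(height_m, weight_kg) {
  h <- check_measure(height_m, "height_m", 0.5, 2.5)
  w <- check_measure(weight_kg, "weight_kg", 20, 300)
  w / h^2
}

#' Grade BMI into the item-10 deficit levels
#'
#' Default mapping uses the WHO adult bands with underweight pooled into
#' the intermediate grade (underweight is itself a deficit in elderly
#' cohorts): Normal (weight 0) for 18.5 <= BMI < 25; Moderate (0.5) for
#' BMI < 18.5 or 25 <= BMI < 30; Severe (1) for BMI >= 30.
#'
#' @param bmi numeric vector of BMI values (kg/m^2), positive.
#' @param cuts named list overriding the default cut points: `normal_lo`
#'   (18.5), `normal_hi` (25), `severe_lo` (30).
#' @return A data.frame (class `fi30_graded`) with `label` and `weight`.
#' @examples
#' grade_bmi(c(22, 27, 31))$weight  # 0 0.5 1
#' @export
grade_bmi <- function(bmi, cuts = list()) {
  bmi <- as.numeric(bmi)
  if (any(!is.na(bmi) & bmi <= 0)) {
    fi30_stop("fi30_domain_error", "bmi must be positive")
  }
  lo <- cuts$normal_lo %||% 18.5
  hi <- cuts$normal_hi %||% 25
  sev <- cuts$severe_lo %||% 30
  w <- ifelse(is.na(bmi), NA_real_,
       ifelse(bmi >= sev, 1,
       ifelse(bmi >= lo & bmi < hi, 0, 0.5)))
  graded_level(c("Severe", "Moderate", "Normal")[match(w, c(1, 0.5, 0))], w)
}

#' Grade random blood sugar into the item-17 deficit levels
#'
#' Instrument bands: weight 0 below 7.9 mmol/L, 0.5 for 7.9 up to (but not
#' including) 15.0, and 1 at 15.0 or more. The interval is half-open on
#' the right so every non-negative value is assignable.
#'
#' @param rbs random blood sugar in mmol/L, non-negative; vectorized.
#' @return A data.frame (class `fi30_graded`) with `label` and `weight`.
#' @examples
#' grade_rbs(c(7, 10, 15))$weight  # 0 0.5 1
#' @export
grade_rbs <- function(rbs) {
  rbs <- as.numeric(rbs)
  if (any(!is.na(rbs) & rbs < 0)) {
    fi30_stop("fi30_domain_error", "rbs must be non-negative")
  }
  w <- ifelse(is.na(rbs), NA_real_,
       ifelse(rbs >= 15, 1, ifelse(rbs >= 7.9, 0.5, 0)))
  graded_level(c("High", "Elevated", "Normal")[match(w, c(1, 0.5, 0))], w)
}

#' Grade blood pressure into the item-22 deficit levels
#'
#' Default mapping follows the WHO/ISH hypertension grades, taking the
#' worse of the systolic and diastolic grade: Normal (0) below 140/90;
#' Mild (0.33) at 140-159 or 90-99; Moderate (0.66) at 160-179 or
#' 100-109; Severe (1) at >= 180 or >= 110. Up to three readings per
#' subject may be averaged upstream with [mean_bp()].
#'
#' @param sbp systolic pressure, mmHg; vectorized.
#' @param dbp diastolic pressure, mmHg; must be below `sbp`.
#' @param cuts named list overriding the grade thresholds: `sbp` (default
#'   `c(140, 160, 180)`) and `dbp` (default `c(90, 100, 110)`), each
#'   strictly increasing lower bounds of the Mild/Moderate/Severe grades.
#' @return A data.frame (class `fi30_graded`) with `label` and `weight`.
#' @examples
#' grade_bp(c(120, 150, 185), c(80, 85, 95))$label
#' @export
grade_bp <- function(sbp, dbp, cuts = list()) {
  sbp <- check_measure(sbp, "sbp_mmhg", 0)
  dbp <- check_measure(dbp, "dbp_mmhg", 0)
  bad <- !is.na(sbp) & !is.na(dbp) & sbp <= dbp
  if (any(bad)) {
    fi30_stop("fi30_validation_error",
              "systolic pressure must exceed diastolic pressure")
  }
  s_cut <- cuts$sbp %||% c(140, 160, 180)
  d_cut <- cuts$dbp %||% c(90, 100, 110)
  grade_one <- function(x, cut) findInterval(x, cut)
  g <- pmax(grade_one(sbp, s_cut), grade_one(dbp, d_cut))
  w <- c(0, 0.33, 0.66, 1)[g + 1L]
  graded_level(c("Normal", "Mild", "Moderate", "Severe")[g + 1L], w)
}

#' Average repeated blood-pressure readings
#'
#' Convenience helper for the measurement protocol of averaging up to
#' three consecutive readings before grading.
#'
#' @param ... numeric vectors of readings (one vector per reading,
#'   recycled subject-wise).
#' @return Numeric vector of per-subject means, ignoring missing readings.
#' @export
mean_bp <- function(...) {
  rowMeans(cbind(...), na.rm = TRUE)
}

#' Grade a GDS-15 total into the item-20 deficit levels
#'
#' Default mapping uses the standard GDS-15 screening bands matched to the
#' instrument's three labels: total 0-4 normal (0), 5-9 moderate
#' depression (0.5), 10-15 severe depression (1).
#'
#' @param gds_total integer total score in 0..15; vectorized.
#' @param cuts named list overriding the band lower bounds: `moderate_lo`
#'   (5), `severe_lo` (10).
#' @return A data.frame (class `fi30_graded`) with `label` and `weight`.
#' @examples
#' grade_gds(c(0, 7, 12))$weight  # 0 0.5 1
#' @export
grade_gds <- function(gds_total, cuts = list()) {
  g <- as.numeric(gds_total)
  ok <- is.na(g) | (g >= 0 & g <= 15 & g == round(g))
  if (!all(ok)) {
    fi30_stop("fi30_domain_error",
              sprintf("gds_total must be an integer in 0..15; got %s",
                      paste(unique(g[!ok]), collapse = ", ")))
  }
  mod <- cuts$moderate_lo %||% 5
  sev <- cuts$severe_lo %||% 10
  w <- ifelse(is.na(g), NA_real_, ifelse(g >= sev, 1, ifelse(g >= mod, 0.5, 0)))
  graded_level(c("Severe depression", "Moderate depression",
                 "Normal depression")[match(w, c(1, 0.5, 0))], w)
}
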