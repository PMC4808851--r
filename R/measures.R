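#' Impedance magnitude from resistance and reactance
#'
#' Combines the resistive (R) and capacitive (Xc) components of a 50 kHz
#' whole-body bioimpedance measurement into the impedance modulus
#' \eqn{Z = \sqrt{R^2 + Xc^2}}. An arithmetic-sum variant (`R + Xc`) is kept
#' behind `method = "sum"` because some older reports describe Z that way;
#' it is never the default since only the vector magnitude is consistent
#' with how analyzers report Z.
#'
#' @param resistance Resistance in ohms; must be positive.
#' @param reactance Reactance in ohms; must be non-negative.
#' @param method `"magnitude"` (default, the vector modulus) or `"sum"`.
#' @return Impedance in ohms, same length as the inputs.
#' @examples
#' impedance_magnitude(483.8, 63.0) # 487.9 ohm
#' @export
impedance_magnitude <- function(resistance, reactance,
                                method = c("magnitude", "sum")) {
  method <- match.arg(method)
  check_numeric(resistance, "resistance")
  check_numeric(reactance, "reactance")
  if (any(resistance <= 0)) stop("`resistance` must be positive", call. = FALSE)
  if (any(reactance < 0)) stop("`reactance` must be non-negative", call. = FALSE)
  if (method == "sum") resistance + reactance else sqrt(resistance^2 + reactance^2)
}

#' Body mass index
#'
#' @param weight Body weight in kg; positive.
#' @param stature Stature in cm; positive.
#' @return BMI in kg/m^2.
#' @examples
#' body_mass_index(70.0, 175.8) # 22.6 kg/m^2
#' @export
body_mass_index <- function(weight, stature) {
  check_numeric(weight, "weight")
  check_numeric(stature, "stature")
  if (any(weight <= 0)) stop("`weight` must be positive", call. = FALSE)
  if (any(stature <= 0)) stop("`stature` must be positive", call. = FALSE)
  weight / (stature / 100)^2
}

#' Reference fat-free mass from DXA components
#'
#' DXA partitions body mass into fat mass, bone mineral content (BMC) and
#' lean soft tissue (LST); the fat-free mass reference is their fat-free sum,
#' FFM = BMC + LST.
#'
#' @param bmc Bone mineral content in kg; non-negative.
#' @param lst Lean soft tissue in kg; non-negative.
#' @return Fat-free mass in kg.
#' @examples
#' ffm_reference(3.0, 55.2) # 58.2 kg
#' @export
ffm_reference <- function(bmc, lst) {
  check_numeric(bmc, "bmc")
  check_numeric(lst, "lst")
  if (any(bmc < 0)) stop("`bmc` must be non-negative", call. = FALSE)
  if (any(lst < 0)) stop("`lst` must be non-negative", call. = FALSE)
  bmc + lst
}

#' Impedance index (stature squared over resistance)
#'
#' The dominant single-frequency BIA predictor of fat-free mass,
#' proportional to conductive body volume. Stature enters in cm, so the
#' index carries units cm^2/ohm.
#'
#' @param stature Stature in cm; positive.
#' @param resistance Resistance in ohms; positive.
#' @return Impedance index in cm^2/ohm.
#' @export
impedance_index <- function(stature, resistance) {
  check_numeric(stature, "stature")
  check_numeric(resistance, "resistance")
  if (any(stature <= 0)) stop("`stature` must be positive", call. = FALSE)
  if (any(resistance <= 0)) stop("`resistance` must be positive", call. = FALSE)
  stature^2 / resistance
}

#' Add derived measures to a cohort
#'
#' Computes per-subject derived quantities from the raw cohort columns:
#' BMI (`bmi`), impedance modulus (`impedance_ohm`), the DXA reference
#' fat-free mass (`ffm_dxa_kg = bmc_kg + lst_kg`), the impedance index
#' (`impedance_index`, cm^2/ohm) and its base-10 logarithm
#' (`log_impedance_index`). DXA columns may be absent or NA
#' (prediction-only cohorts); `ffm_dxa_kg` is then NA.
#'
#' @param cohort A cohort data frame (see [read_cohort()] for the schema).
#' @return The cohort as a tibble with derived columns appended.
#' @export
derive_measures <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  require_columns(cohort, c("weight_kg", "stature_cm", "resistance_ohm", "reactance_ohm"))
  cohort$bmi <- body_mass_index(cohort$weight_kg, cohort$stature_cm)
  cohort$impedance_ohm <- impedance_magnitude(cohort$resistance_ohm, cohort$reactance_ohm)
  if (all(c("bmc_kg", "lst_kg") %in% names(cohort))) {
    ok <- !is.na(cohort$bmc_kg) & !is.na(cohort$lst_kg)
    cohort$ffm_dxa_kg <- NA_real_
    if (any(ok)) {
      cohort$ffm_dxa_kg[ok] <- ffm_reference(cohort$bmc_kg[ok],
                                             cohort$lst_kg[ok])
    }
  } else {
    cohort$ffm_dxa_kg <- NA_real_
  }
  cohort$impedance_index <- impedance_index(cohort$stature_cm, cohort$resistance_ohm)
  cohort$log_impedance_index <- log10(cohort$impedance_index)
  cohort
}

#' Validate a cohort against the subject-record invariants
#'
#' Checks positivity of anthropometry and bioimpedance, non-negativity of
#' DXA components, and (when DXA columns are present) that the DXA mass
#' components approximately close to scale weight:
#' |fm + bmc + lst - weight| <= `mass_tol`. DXA and scale disagree in real
#' data, hence the tolerance.
#'
#' @param cohort Cohort data frame.
#' @param mass_tol Allowed |FM + BMC + LST - weight| discrepancy in kg.
#' @return The cohort, invisibly, if all checks pass; otherwise an error.
#' @export
validate_cohort <- function(cohort, mass_tol = 3.0) {
  require_columns(cohort, c(
    "subject_id", "age", "sex", "weight_kg", "stature_cm",
    "resistance_ohm", "reactance_ohm"
  ))
  if (any(cohort$weight_kg <= 0)) stop("weight_kg must be positive", call. = FALSE)
  if (any(cohort$stature_cm <= 0)) stop("stature_cm must be positive", call. = FALSE)
  if (any(cohort$age <= 0)) stop("age must be positive", call. = FALSE)
  if (any(cohort$resistance_ohm <= 0)) stop("resistance_ohm must be positive", call. = FALSE)
  if (any(cohort$reactance_ohm < 0)) stop("reactance_ohm must be non-negative", call. = FALSE)
  if (!all(cohort$sex %in% c(0, 1))) {
    stop("sex must be coded 0 (female) or 1 (male)", call. = FALSE)
  }
  dxa <- c("fm_kg", "bmc_kg", "lst_kg")
  if (all(dxa %in% names(cohort))) {
    have <- stats::complete.cases(cohort[dxa])
    if (any(have)) {
      d <- cohort[have, ]
      if (any(d$fm_kg < 0 | d$bmc_kg < 0 | d$lst_kg < 0)) {
        stop("DXA components must be non-negative", call. = FALSE)
      }
      gap <- abs(d$fm_kg + d$bmc_kg + d$lst_kg - d$weight_kg)
      if (any(gap > mass_tol)) {
        stop(sprintf(
          "DXA components disagree with scale weight by up to %.2f kg (tolerance %.2f kg)",
          max(gap), mass_tol
        ), call. = FALSE)
      }
    }
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' One row per subject; header columns `subject_id, age, sex, weight_kg,
#' stature_cm, resistance_ohm, reactance_ohm, fm_kg, bmc_kg, lst_kg`
#' (decimal point, UTF-8). DXA columns may be missing or NA for
#' prediction-only cohorts.
#'
#' @param path Path to the CSV file.
#' @param validate Run [validate_cohort()] on the result (default TRUE).
#' @param mass_tol Passed to [validate_cohort()].
#' @return A tibble, one row per subject.
#' @export
read_cohort <- function(path, validate = TRUE, mass_tol = 3.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df <- tibble::as_tibble(df)
  if (validate) validate_cohort(df, mass_tol = mass_tol)
  df
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# internal -------------------------------------------------------------

check_numeric <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

require_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
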