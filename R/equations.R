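#' Catalogue of fat-free mass prediction equations
#'
#' Returns the nine evaluable single-frequency (50 kHz) BIA equations for
#' fat-free mass handled by this package: eight published whole-body
#' equations (`eq1`..`eq8`) plus the population-specific equation for young
#' male military cadets developed against a DXA reference (`specific`).
#' Each entry records its source, criterion method, required inputs, the
#' coefficients exactly as published, and the published fit statistics
#' where reported.
#'
#' Unit conventions follow the original publications: the impedance index
#' terms S^2/R and S^2/Z always take stature in cm (cm^2/ohm), while the
#' standalone stature terms of `eq4` and `eq5` take stature in meters.
#' Sex is coded 0 = female, 1 = male. `eq7`'s published SEE is a
#' percentage, not kg, and is stored as published.
#'
#' @return A named list of equation specifications (class
#'   `ffm_equation_spec`): fields `equation_id`, `source`, `criterion`,
#'   `formula_text`, `required_inputs`, `coefficients`, `reference_r2`,
#'   `reference_see`, `see_unit`.
#' @examples
#' length(equation_catalogue())  # 9
#' equation_catalogue()[["eq3"]]$coefficients
#' @export
equation_catalogue <- function() {
  spec <- function(id, source, criterion, formula_text, required_inputs,
                   coefficients, reference_r2 = NA_real_,
                   reference_see = NA_real_, see_unit = "kg") {
    structure(
      list(
        equation_id = id, source = source, criterion = criterion,
        formula_text = formula_text, required_inputs = required_inputs,
        coefficients = coefficients, reference_r2 = reference_r2,
        reference_see = reference_see, see_unit = see_unit
      ),
      class = "ffm_equation_spec"
    )
  }
  list(
    eq1 = spec(
      "eq1", "Lukaski et al. 1988", "UW",
      "0.734*(S^2/R) + 0.116*Wt + 0.096*Xc + 0.878*Sex - 4.03",
      c("stature_cm", "resistance_ohm", "weight_kg", "reactance_ohm", "sex"),
      c(s2_over_r = 0.734, weight = 0.116, reactance = 0.096,
        sex = 0.878, intercept = -4.03),
      reference_r2 = 0.99, reference_see = 2.2
    ),
    eq2 = spec(
      "eq2", "Chumlea et al. 1990", "UW",
      "0.87*(S^2/Z) + 3.50",
      c("stature_cm", "resistance_ohm", "reactance_ohm"),
      c(s2_over_z = 0.87, intercept = 3.50),
      reference_r2 = 0.81, reference_see = 3.0
    ),
    eq3 = spec(
      "eq3", "Segal et al. 1988", "UW",
      "0.00132*S^2 - 0.04394*R + 0.3052*Wt - 0.1676*Age + 22.66827",
      c("stature_cm", "resistance_ohm", "weight_kg", "age"),
      c(s2 = 0.00132, resistance = -0.04394, weight = 0.3052,
        age = -0.1676, intercept = 22.66827),
      reference_r2 = 0.9, reference_see = 3.6
    ),
    eq4 = spec(
      "eq4", "Deurenberg et al. 1989", "UW",
      "0.438*(S^2/Z) + 0.308*Wt + 1.6*Sex + 7.04*S_m - 8.50",
      c("stature_cm", "resistance_ohm", "reactance_ohm", "weight_kg", "sex"),
      c(s2_over_z = 0.438, weight = 0.308, sex = 1.6,
        stature_m = 7.04, intercept = -8.50),
      reference_r2 = 0.99, reference_see = 2.4
    ),
    eq5 = spec(
      "eq5", "Deurenberg et al. 1991", "UW",
      "0.34*(S^2/Z) - 0.127*Age + 0.273*Wt + 4.56*Sex + 15.34*S_m - 12.44",
      c("stature_cm", "resistance_ohm", "reactance_ohm", "age", "weight_kg", "sex"),
      c(s2_over_z = 0.34, age = -0.127, weight = 0.273, sex = 4.56,
        stature_m = 15.34, intercept = -12.44),
      reference_r2 = 0.93, reference_see = 2.6
    ),
    eq6 = spec(
      "eq6", "Lohman 1992", "UW",
      "0.485*(S^2/R) + 0.338*Wt + 5.32",
      c("stature_cm", "resistance_ohm", "weight_kg"),
      c(s2_over_r = 0.485, weight = 0.338, intercept = 5.32),
      reference_r2 = NA_real_, reference_see = 2.9
    ),
    eq7 = spec(
      "eq7", "Kotler et al. 1996", "DXA",
      "0.50*(S^1.48/Z^0.55)*(1.0/1.21) + 0.42*Wt + 0.49",
      c("stature_cm", "resistance_ohm", "reactance_ohm", "weight_kg"),
      c(index = 0.50, stature_power = 1.48, impedance_power = 0.55,
        scale = 1.0 / 1.21, weight = 0.42, intercept = 0.49),
      reference_r2 = 0.9, reference_see = 5.0, see_unit = "%"
    ),
    eq8 = spec(
      "eq8", "Sun et al. 2003", "4C",
      "0.65*(S^2/R) + 0.26*Wt + 0.02*R - 10.68",
      c("stature_cm", "resistance_ohm", "weight_kg"),
      c(s2_over_r = 0.65, weight = 0.26, resistance = 0.02,
        intercept = -10.68),
      reference_r2 = 0.90, reference_see = 3.9
    ),
    specific = spec(
      "specific", "this package's target population (young male cadets)", "DXA",
      "0.508*Wt + 39.234*log10(S^2/R) - 48.263",
      c("weight_kg", "stature_cm", "resistance_ohm"),
      c(weight = 0.508, log_s2_over_r = 39.234, intercept = -48.263)
    )
  )
}

#' Predict fat-free mass with a catalogue equation
#'
#' Evaluates one catalogue equation for every subject of a cohort. Raw
#' inputs are taken from the cohort columns; impedance is derived as the
#' vector magnitude of resistance and reactance where the equation needs Z.
#' A missing or NA required input is an error naming the offending field.
#'
#' @param cohort Cohort data frame (schema of [read_cohort()]).
#' @param equation Equation id: one of `eq1`..`eq8`, `specific`.
#' @return Numeric vector of FFM estimates in kg, aligned with the cohort
#'   rows.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 5), seed = 1)
#' predict_ffm(cohort, "eq3")
#' @export
predict_ffm <- function(cohort, equation) {
  catalogue <- equation_catalogue()
  if (!is.character(equation) || length(equation) != 1 ||
      !equation %in% names(catalogue)) {
    stop("unknown equation id: ", paste(equation, collapse = ", "),
         "; known ids: ", paste(names(catalogue), collapse = ", "),
         call. = FALSE)
  }
  spec <- catalogue[[equation]]
  cohort <- tibble::as_tibble(cohort)
  for (col in spec$required_inputs) {
    if (!col %in% names(cohort) || anyNA(cohort[[col]])) {
      stop(sprintf("equation '%s' requires input '%s', which is missing or NA",
                   equation, col), call. = FALSE)
    }
  }
  s <- cohort$stature_cm
  wt <- if ("weight_kg" %in% spec$required_inputs) cohort$weight_kg
  r <- if ("resistance_ohm" %in% spec$required_inputs) cohort$resistance_ohm
  xc <- if ("reactance_ohm" %in% spec$required_inputs) cohort$reactance_ohm
  z <- if (!is.null(r) && !is.null(xc)) impedance_magnitude(r, xc)
  cf <- spec$coefficients
  out <- switch(
    equation,
    eq1 = cf[["s2_over_r"]] * (s^2 / r) + cf[["weight"]] * wt +
      cf[["reactance"]] * xc + cf[["sex"]] * cohort$sex + cf[["intercept"]],
    eq2 = cf[["s2_over_z"]] * (s^2 / z) + cf[["intercept"]],
    eq3 = cf[["s2"]] * s^2 + cf[["resistance"]] * r + cf[["weight"]] * wt +
      cf[["age"]] * cohort$age + cf[["intercept"]],
    eq4 = cf[["s2_over_z"]] * (s^2 / z) + cf[["weight"]] * wt +
      cf[["sex"]] * cohort$sex + cf[["stature_m"]] * (s / 100) +
      cf[["intercept"]],
    eq5 = cf[["s2_over_z"]] * (s^2 / z) + cf[["age"]] * cohort$age +
      cf[["weight"]] * wt + cf[["sex"]] * cohort$sex +
      cf[["stature_m"]] * (s / 100) + cf[["intercept"]],
    eq6 = cf[["s2_over_r"]] * (s^2 / r) + cf[["weight"]] * wt +
      cf[["intercept"]],
    eq7 = cf[["index"]] * (s^cf[["stature_power"]] / z^cf[["impedance_power"]]) *
      cf[["scale"]] + cf[["weight"]] * wt + cf[["intercept"]],
    eq8 = cf[["s2_over_r"]] * (s^2 / r) + cf[["weight"]] * wt +
      cf[["resistance"]] * r + cf[["intercept"]],
    specific = predict_specific(wt, s, r)
  )
  if (any(!is.finite(out))) {
    stop(sprintf("equation '%s' produced non-finite estimates", equation),
         call. = FALSE)
  }
  unname(out)
}

#' Population-specific fat-free mass equation
#'
#' The cadet-specific equation developed by stepwise regression on a DXA
#' reference: `FFM = 0.508 * Wt + 39.234 * log10(S^2/R) - 48.263`, with
#' weight in kg, stature in cm, resistance in ohms. Strictly increasing in
#' weight and stature, strictly decreasing in resistance.
#'
#' @param weight Body weight in kg; positive.
#' @param stature Stature in cm; positive.
#' @param resistance Resistance in ohms; positive.
#' @return Fat-free mass estimate in kg.
#' @examples
#' predict_specific(70.0, 175.8, 479.5) # 58.28 kg
#' @export
predict_specific <- function(weight, stature, resistance) {
  check_numeric(weight, "weight")
  check_numeric(stature, "stature")
  check_numeric(resistance, "resistance")
  if (any(weight <= 0)) stop("`weight` must be positive", call. = FALSE)
  if (any(stature <= 0)) stop("`stature` must be positive", call. = FALSE)
  if (any(resistance <= 0)) stop("`resistance` must be positive", call. = FALSE)
  0.508 * weight + 39.234 * log10(stature^2 / resistance) - 48.263
}

#' Export the equation catalogue as JSON
#'
#' Writes every catalogue entry (id, citation, criterion, formula,
#' coefficients, units, published fit statistics) as a JSON document for
#' documentation or downstream tooling.
#'
#' @param path Output path; if NULL, the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
catalogue_json <- function(path = NULL) {
  cat_list <- lapply(equation_catalogue(), function(spec) {
    list(
      equation_id = spec$equation_id,
      source = spec$source,
      criterion = spec$criterion,
      formula = spec$formula_text,
      required_inputs = spec$required_inputs,
      coefficients = as.list(spec$coefficients),
      reference_r2 = spec$reference_r2,
      reference_see = spec$reference_see,
      see_unit = spec$see_unit,
      units = list(stature = "cm (standalone stature terms of eq4/eq5: m)",
                   weight = "kg", resistance = "ohm", reactance = "ohm")
    )
  })
  json <- jsonlite::toJSON(cat_list, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.ffm_equation_spec <- function(x, ...) {
  cat(sprintf("<%s> %s (criterion: %s)\n", x$equation_id, x$source, x$criterion))
  cat("  FFM =", x$formula_text, "\n")
  if (!is.na(x$reference_see)) {
    cat(sprintf("  published fit: R2 = %s, SEE = %s %s\n",
                ifelse(is.na(x$reference_r2), "not reported", x$reference_r2),
                x$reference_see, x$see_unit))
  }
  invisible(x)
}
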