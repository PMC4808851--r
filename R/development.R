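#' Random development / cross-validation split
#'
#' Assigns subjects uniformly at random, without replacement, to a
#' development group (DG) and a cross-validation group (CVG). The DG size
#' is round-half-up of `n * dev_fraction`, so a cohort of 396 at the
#' conventional 2:1 ratio yields groups of 264 and 132.
#'
#' @param cohort Cohort data frame.
#' @param dev_fraction Fraction assigned to the development group,
#'   strictly between 0 and 1. Default 2/3.
#' @param seed Integer seed; the split is reproducible given the seed and
#'   the global RNG state is left untouched. NULL uses the current RNG.
#' @return An object of class `cohort_split`: `development` and
#'   `validation` tibbles, the corresponding `development_ids` /
#'   `validation_ids`, and `seed`.
#' @export
split_cohort <- function(cohort, dev_fraction = 2 / 3, seed = NULL) {
  cohort <- tibble::as_tibble(cohort)
  n <- nrow(cohort)
  if (n < 6) stop("cohort too small to split (n >= 6 required)", call. = FALSE)
  if (!is.numeric(dev_fraction) || dev_fraction <= 0 || dev_fraction >= 1) {
    stop("`dev_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  n_dev <- floor(n * dev_fraction + 0.5)
  if (n_dev < 1 || n_dev >= n) {
    stop("`dev_fraction` leaves an empty group", call. = FALSE)
  }
  draw <- function() sample.int(n, n_dev)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  idx <- sort(idx)
  structure(
    list(
      development = cohort[idx, ],
      validation = cohort[-idx, ],
      development_ids = cohort$subject_id[idx],
      validation_ids = cohort$subject_id[-idx],
      seed = seed
    ),
    class = "cohort_split"
  )
}

#' Candidate predictor matrix for equation development
#'
#' The fixed eight-predictor pool screened when developing a new FFM
#' equation: age (y), stature (cm), BMI (kg/m^2), resistance (ohm),
#' reactance (ohm), impedance (ohm), weight (kg), and the base-10
#' logarithm of the impedance index stature^2/R.
#'
#' @param cohort Cohort data frame.
#' @return A tibble with columns `age`, `stature`, `bmi`, `resistance`,
#'   `reactance`, `impedance`, `weight`, `log10_impedance_index`, aligned
#'   with the cohort rows.
#' @export
candidate_predictors <- function(cohort) {
  d <- derive_measures(cohort)
  for (col in c("age", "weight_kg", "stature_cm", "resistance_ohm", "reactance_ohm")) {
    if (anyNA(d[[col]])) {
      stop(sprintf("candidate predictors require complete '%s'", col),
           call. = FALSE)
    }
  }
  tibble::tibble(
    age = d$age,
    stature = d$stature_cm,
    bmi = d$bmi,
    resistance = d$resistance_ohm,
    reactance = d$reactance_ohm,
    impedance = d$impedance_ohm,
    weight = d$weight_kg,
    log10_impedance_index = d$log_impedance_index
  )
}

#' Stepwise multiple linear regression by partial-F p-values
#'
#' Classic bidirectional stepwise selection as implemented in the older
#' commercial statistics packages: at each round the excluded candidate
#' with the smallest entry p-value (the t-test of its coefficient when
#' added to the current model, equivalent to the partial F test) enters if
#' p < `alpha_enter`; then any included predictor whose p-value exceeds
#' `alpha_remove` is dropped (worst first). Iteration stops when no change
#' occurs; revisiting a previously seen model also stops the loop (cycle
#' guard). The final model is refit by ordinary least squares and its
#' residuals are checked for normality with a Shapiro-Wilk test.
#'
#' A candidate that is collinear with the current model (NA coefficient)
#' is skipped with a warning and cannot enter.
#'
#' @param predictors Data frame of candidate predictors (e.g.
#'   [candidate_predictors()]).
#' @param response Numeric response (kg), same length.
#' @param alpha_enter Entry threshold; default 0.05.
#' @param alpha_remove Removal threshold; default 0.10.
#' @return An object of class `ffm_model`: `selected_predictors` (in entry
#'   order), `coefficients` (named, intercept first), `r2_adj`, `see`,
#'   `residual_normality_p`, `n_fit`, and the underlying `lm` fit.
#' @export
stepwise_fit <- function(predictors, response, alpha_enter = 0.05,
                         alpha_remove = 0.10) {
  predictors <- as.data.frame(predictors)
  p <- ncol(predictors)
  n <- length(response)
  if (nrow(predictors) != n) {
    stop("`predictors` and `response` lengths differ", call. = FALSE)
  }
  if (n <= p + 2) {
    stop("too few observations for stepwise OLS over this candidate pool",
         call. = FALSE)
  }
  dat <- cbind(.response = response, predictors)
  fit_for <- function(vars) {
    fml <- if (length(vars)) {
      stats::reformulate(vars, response = ".response")
    } else {
      .response ~ 1
    }
    stats::lm(fml, data = dat)
  }
  coef_p <- function(fit) {
    ct <- summary(fit)$coefficients
    stats::setNames(ct[, "Pr(>|t|)"], rownames(ct))
  }

  included <- character(0)
  seen <- character(0)
  warned_collinear <- character(0)
  repeat {
    state <- paste(sort(included), collapse = "+")
    if (state %in% seen) break
    seen <- c(seen, state)
    changed <- FALSE

    excluded <- setdiff(names(predictors), included)
    if (length(excluded)) {
      entry_p <- vapply(excluded, function(v) {
        fit <- fit_for(c(included, v))
        if (anyNA(stats::coef(fit))) {
          if (!v %in% warned_collinear) {
            warning(sprintf("candidate '%s' is collinear with the current model; skipped", v),
                    call. = FALSE)
            warned_collinear <<- c(warned_collinear, v)
          }
          return(NA_real_)
        }
        coef_p(fit)[[v]]
      }, numeric(1))
      entry_p <- entry_p[!is.na(entry_p)]
      if (length(entry_p) && min(entry_p) < alpha_enter) {
        included <- c(included, names(which.min(entry_p)))
        changed <- TRUE
      }
    }

    repeat {
      if (!length(included)) break
      pv <- coef_p(fit_for(included))
      pv <- pv[setdiff(names(pv), "(Intercept)")]
      if (max(pv) > alpha_remove) {
        included <- setdiff(included, names(which.max(pv)))
        changed <- TRUE
      } else {
        break
      }
    }

    if (!changed) break
  }

  fit <- fit_for(included)
  s <- summary(fit)
  res <- stats::residuals(fit)
  norm_p <- if (stats::sd(res) == 0) 1 else stats::shapiro.test(res)$p.value
  structure(
    list(
      selected_predictors = included,
      coefficients = stats::coef(fit),
      r2_adj = s$adj.r.squared,
      see = s$sigma,
      residual_normality_p = norm_p,
      n_fit = n,
      fit = fit
    ),
    class = "ffm_model"
  )
}

#' Predict fat-free mass from a fitted development model
#'
#' @param object An `ffm_model` from [stepwise_fit()].
#' @param cohort Cohort data frame; the candidate predictors are rebuilt
#'   from its raw columns.
#' @param ... Unused.
#' @return Numeric vector of FFM predictions (kg).
#' @export
predict.ffm_model <- function(object, cohort, ...) {
  newdata <- as.data.frame(candidate_predictors(cohort))
  unname(stats::predict(object$fit, newdata = newdata))
}

#' Develop and cross-validate a population-specific FFM equation
#'
#' The full development procedure: randomly split the cohort 2:1 into
#' development (DG) and cross-validation (CVG) groups, fit a stepwise OLS
#' model of the DXA fat-free mass on the eight-candidate pool using the DG
#' only, then evaluate the fitted equation's agreement with the reference
#' on the DG, the CVG, and the total sample.
#'
#' @param cohort Cohort data frame with a complete DXA reference.
#' @param dev_fraction Development-group fraction; default 2/3.
#' @param seed Integer seed driving the split; NULL uses the current RNG.
#' @param alpha_enter,alpha_remove Stepwise thresholds (see
#'   [stepwise_fit()]).
#' @return An object of class `ffm_development`: `model` (`ffm_model`),
#'   `split` (`cohort_split`), and `dg_report` / `cvg_report` /
#'   `total_report` (`agreement_report`s).
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 120), seed = 7)
#' dev <- develop_and_validate(cohort, seed = 7)
#' dev$model$selected_predictors
#' @export
develop_and_validate <- function(cohort, dev_fraction = 2 / 3, seed = NULL,
                                 alpha_enter = 0.05, alpha_remove = 0.10) {
  cohort <- derive_measures(cohort)
  if (anyNA(cohort$ffm_dxa_kg)) {
    stop("development requires a complete DXA reference (bmc_kg + lst_kg)",
         call. = FALSE)
  }
  split <- split_cohort(cohort, dev_fraction = dev_fraction, seed = seed)
  model <- stepwise_fit(
    candidate_predictors(split$development),
    split$development$ffm_dxa_kg,
    alpha_enter = alpha_enter, alpha_remove = alpha_remove
  )
  report_on <- function(id, group) {
    build_report(id, predict(model, group), group$ffm_dxa_kg)
  }
  structure(
    list(
      model = model,
      split = split,
      dg_report = report_on("specific_dg", split$development),
      cvg_report = report_on("specific_cvg", split$validation),
      total_report = report_on("specific_total", cohort)
    ),
    class = "ffm_development"
  )
}

#' Serialize a development result to JSON
#'
#' Coefficients, selection order, fit diagnostics and the three per-group
#' agreement reports at full precision.
#'
#' @param result An `ffm_development` object.
#' @param path Output path; if NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
development_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "ffm_development"))
  strip <- function(r) unclass(r)
  payload <- list(
    model = list(
      selected_predictors = result$model$selected_predictors,
      coefficients = as.list(result$model$coefficients),
      r2_adj = result$model$r2_adj,
      see = result$model$see,
      residual_normality_p = result$model$residual_normality_p,
      n_fit = result$model$n_fit
    ),
    split = list(
      n_development = nrow(result$split$development),
      n_validation = nrow(result$split$validation),
      seed = result$split$seed
    ),
    reports = list(
      dg = strip(result$dg_report),
      cvg = strip(result$cvg_report),
      total = strip(result$total_report)
    )
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @export
print.ffm_development <- function(x, ...) {
  cf <- x$model$coefficients
  terms <- names(cf)[names(cf) != "(Intercept)"]
  rhs <- paste(sprintf("%.3f*%s", cf[terms], terms), collapse = " + ")
  cat("Population-specific FFM equation (stepwise OLS on the development group)\n")
  cat(sprintf("  FFM = %s %+.3f\n", rhs, cf[["(Intercept)"]]))
  cat(sprintf("  DG n = %d, adj R2 = %.2f, SEE = %.1f kg, residual normality p = %.3f\n",
              x$model$n_fit, x$model$r2_adj, x$model$see,
              x$model$residual_normality_p))
  for (r in list(x$dg_report, x$cvg_report, x$total_report)) {
    cat(sprintf("  %-14s n=%3d  diff %.1f +/- %.1f kg  CCC %.2f  SEE %.1f  PE %.1f\n",
                r$equation_id, r$n, r$mean_diff, r$sd_diff, r$ccc, r$see,
                r$pure_error))
  }
  invisible(x)
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("Cohort split: development n = %d, validation n = %d (seed %s)\n",
              nrow(x$development), nrow(x$validation),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
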